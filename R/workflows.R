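# End-to-end workflows tying the stages into the two analyses the package
# supports: oligomeric-state classification of an experimental SAXS curve,
# and the dimer-to-hexamer interface-mutant design screen. Each writes a
# JSON report embedding the package version, the full configuration
# snapshot, seeds and input checksums.

#' Default run configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' interfacial proximity cutoff 5.5 Angstrom, hydrogen-bond cutoff 3.6
#' Angstrom, salt-bridge cutoff 4.0 Angstrom, side-chain orientation
#' criterion 9 Angstrom / 90 degrees, Guinier limit q*Rg <= 1.5, and the
#' screen settings (50 samples, 5 finalists, 0.3 Angstrom jitter, 12
#' Angstrom relaxation sphere, surrogate score weights).
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `oligoshift_config`.
#' @export
oligoshift_config <- function(...) {
  cfg <- list(
    contact_cutoff = 5.5, hbond_cutoff = 3.6, salt_bridge_cutoff = 4.0,
    orientation_cutoff = 9, orientation_angle = 90,
    qrg_limit = 1.5,
    n_samples = 50, finalists = 5, perturb_sigma = 0.3, relax_radius = 12,
    weights = surrogate_weights(),
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "oligoshift_config")
}

#' @keywords internal
report_header <- function(config, inputs, seed) {
  list(
    tool = "oligoshift",
    version = as.character(utils::packageVersion("oligoshift")),
    seed = seed,
    config = unclass(config),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
}

#' Oligomeric-state classification workflow
#'
#' Reads an experimental SAXS curve and candidate assembly models, runs a
#' Guinier fit, chi-fits every candidate, calls the state, and writes a JSON
#' report plus a plot-ready TSV of residuals to the output directory.
#'
#' @param data_path 2- or 3-column SAXS text file.
#' @param model_paths Named character vector of candidate PDB paths (names
#'   become candidate labels; unnamed paths are labelled by file name).
#' @param out_dir Output directory (created if needed).
#' @param config An [oligoshift_config()].
#' @param measured_mass,subunit_mass Optional masses in kDa for the
#'   mass-consistency check.
#' @return Invisibly, the `oligomer_call`.
#' @export
run_classify_workflow <- function(data_path, model_paths, out_dir = ".",
                                  config = oligoshift_config(),
                                  measured_mass = NULL, subunit_mass = NULL) {
  for (p in c(data_path, model_paths)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- names(model_paths)
  if (is.null(labels)) labels <- rep("", length(model_paths))
  labels[!nzchar(labels)] <-
    sub("\\.pdb$", "", basename(model_paths[!nzchar(labels)]))
  exp_prof <- read_saxs(data_path)
  models <- stats::setNames(lapply(model_paths, read_pdb), labels)
  gfit <- guinier_fit(exp_prof, qrg_limit = config$qrg_limit)
  call <- classify_oligomer(exp_prof, models, measured_mass = measured_mass,
                            subunit_mass = subunit_mass)
  resid_tbl <- dplyr::bind_rows(lapply(call$fits, tidy.saxs_fit))
  utils::write.table(resid_tbl, file.path(out_dir, "fit_residuals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- c(
    report_header(config, c(data_path, unname(model_paths)), config$seed),
    list(
      guinier = unclass(tidy.guinier_fit(gfit))[c("I0", "Rg", "q_max_used",
                                                  "n_points", "r_squared")],
      chis = as.list(call$chis),
      best_model = call$best_model,
      subunit_count = if (is.na(call$subunit_count)) NULL else call$subunit_count,
      mass_consistent = if (is.na(call$mass_consistent)) NULL else call$mass_consistent
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(call)
}

#' Dimer-to-multimer design workflow
#'
#' Derives the template's symmetry definition, locates interfacial positions
#' where the candidate subunit's sequence differs from the template, runs the
#' combinatorial mutant screen, and writes the ranked candidate TSV, the
#' selected mutant assembly as PDB, and a JSON report.
#'
#' @param subunit_path PDB of the candidate subunit (single chain used as the
#'   screening monomer).
#' @param template_path PDB of the template multimer (with partition REMARKs
#'   or an even number of chains, paired into dimers).
#' @param out_dir Output directory.
#' @param config An [oligoshift_config()].
#' @return Invisibly, the `design_screen`.
#' @export
run_design_workflow <- function(subunit_path, template_path, out_dir = ".",
                                config = oligoshift_config()) {
  for (p in c(subunit_path, template_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  template <- read_pdb(template_path)
  subunit <- read_pdb(subunit_path)
  chains <- assembly_chains(template)
  if (length(chains) < 2) stop("template is not a multimer")
  part <- partition(template)
  if (length(unique(part)) < 2) {
    if (length(chains) %% 2 != 0) {
      stop("template has no partition REMARKs and an odd chain count; ",
           "cannot pair chains into dimers")
    }
    part <- stats::setNames(
      paste0("dimer", rep(LETTERS[seq_len(length(chains) / 2)], each = 2)),
      chains
    )
    partition(template) <- part
  }
  first_chain <- assembly_chains(subunit)[1]
  cand_seq <- chain_sequence(subunit, first_chain)
  sub_one <- assembly(subunit[subunit$chain == first_chain, ])
  sites_tbl <- differing_interface_sites(
    template, cand_seq,
    proximity_cutoff = config$contact_cutoff,
    orientation_cutoff = config$orientation_cutoff,
    orientation_angle = config$orientation_angle
  )
  if (!nrow(sites_tbl)) stop("no differing interfacial sites between template and candidate")
  # screen mutations that graft the template residue onto the candidate
  sites <- tibble::tibble(position = sites_tbl$position,
                          wild_aa = sites_tbl$candidate_aa,
                          mutant_aa = sites_tbl$template_aa)
  symdef <- derive_symmetry(template)
  screen <- run_screen(sub_one, sites, symdef,
                       n_samples = config$n_samples,
                       finalists = config$finalists,
                       perturb_sigma = config$perturb_sigma,
                       seed = config$seed, weights = config$weights,
                       relax_radius = config$relax_radius)
  utils::write.table(screen$candidates[order(screen$candidates$rank), ],
                     file.path(out_dir, "screen_ranked.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pdb(screen$selected_assembly, file.path(out_dir, "selected_mutant.pdb"))
  report <- c(
    report_header(config, c(subunit_path, template_path), config$seed),
    list(
      sites = lapply(seq_len(nrow(sites)), function(i) {
        list(position = sites$position[i], wild = sites$wild_aa[i],
             mutant = sites$mutant_aa[i])
      }),
      point_group = symdef$point_group,
      n_candidates = nrow(screen$candidates),
      selected = screen$selected,
      selected_mutations = screen$selected_mutations
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(screen)
}
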
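#' Construct a SAXS profile
#'
#' A scattering profile is a tibble with a strictly increasing scattering
#' vector grid `q` (inverse Angstrom, q = 4 pi sin(theta) / lambda), an
#' `intensity` column (arbitrary units) and an optional `sigma` uncertainty
#' column. It is the unit of every curve comparison in the package.
#'
#' @param q Strictly increasing numeric vector, 1/Angstrom.
#' @param intensity Finite intensities, same length as `q`.
#' @param sigma Optional strictly positive uncertainties.
#' @param label Profile label used in reports and plots.
#' @return A tibble of class `saxs_profile`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, label = "profile") {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(diff(q) <= 0)) stop("q grid must be strictly increasing")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  tb <- tibble::tibble(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(!is.finite(sigma) | sigma <= 0)) stop("sigma must be strictly positive")
    tb$sigma <- sigma
  }
  structure(tb, label = label,
            class = c("saxs_profile", class(tibble::tibble())))
}

#' Read a SAXS profile from 2- or 3-column text
#'
#' Whitespace-separated `q I [sigma]` rows; lines starting with `#` are
#' comments (the common ATSAS-style `.dat` dialect).
#'
#' @param path Input path.
#' @param label Optional label (defaults to the file name).
#' @return A [saxs_profile()].
#' @export
read_saxs <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\\s+")
  ncol <- unique(lengths(fields))
  if (!length(fields) || !all(ncol %in% 2:3)) {
    stop("expected 2- or 3-column whitespace-separated data in ", path)
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = ncol[1],
                               byrow = TRUE))
  if (anyNA(m)) stop("non-numeric data row in ", path)
  saxs_profile(m[, 1], m[, 2],
               sigma = if (ncol[1] == 3) m[, 3] else NULL, label = label)
}

#' Write a SAXS profile as 3-column text
#'
#' @param profile A [saxs_profile()].
#' @param path Output path.
#' @param header Optional extra `#` header lines.
#' @return Invisibly, `path`.
#' @export
write_saxs <- function(profile, path, header = character(0)) {
  has_sigma <- "sigma" %in% names(profile)
  cols <- if (has_sigma) "# q intensity sigma" else "# q intensity"
  body <- if (has_sigma) {
    sprintf("%.8g %.8g %.8g", profile$q, profile$intensity, profile$sigma)
  } else {
    sprintf("%.8g %.8g", profile$q, profile$intensity)
  }
  writeLines(c(paste0("# ", attr(profile, "label")), header, cols, body), path)
  invisible(path)
}

#' @keywords internal
#' One scatterer per residue at its heavy-atom centroid with the residue
#' electron count as form factor, or one per atom with element electrons.
scatterer_table <- function(model, granularity = c("residue", "atom")) {
  granularity <- match.arg(granularity)
  model <- check_assembly(model)
  if (granularity == "atom") {
    f <- unname(element_electrons[model$element])
    f[is.na(f)] <- 6  # unknown elements counted as carbon
    return(list(xyz = coords_matrix(model), f = f))
  }
  key <- paste(model$chain, model$seq_id, model$ins, sep = "\r")
  idx <- split(seq_len(nrow(model)), key)
  xyz <- t(vapply(idx, function(ii) colMeans(coords_matrix(model[ii, , drop = FALSE])),
                  numeric(3)))
  aa <- vapply(idx, function(ii) model$aa[ii[1]], character(1))
  f <- unname(aa_residue_electrons[aa])
  f[is.na(f)] <- mean(aa_residue_electrons)  # unknown residue: average weight
  list(xyz = xyz, f = f)
}

#' Theoretical scattering profile by the Debye formula
#'
#' Computes `I(q) = sum_i sum_j f_i f_j sin(q r_ij) / (q r_ij)` (with the
#' sinc limit 1 at `q r = 0`) over constant form factors: per-residue electron
#' counts at residue granularity (the default; scatterers at heavy-atom
#' centroids) or per-atom electron counts at atom granularity. This is a
#' vacuum Debye sum: hydration-layer and excluded-volume corrections are
#' deliberately not modelled, since classification among oligomeric
#' candidates rests on shape.
#'
#' @param model An [assembly()].
#' @param q_grid Scattering vector grid (1/Angstrom); `q = 0` is allowed.
#' @param granularity `"residue"` (default) or `"atom"`.
#' @return A [saxs_profile()] labelled by the granularity.
#' @export
debye_profile <- function(model, q_grid, granularity = c("residue", "atom")) {
  granularity <- match.arg(granularity)
  sc <- scatterer_table(model, granularity)
  n <- nrow(sc$xyz)
  if (!n) stop("empty model")
  q_grid <- as.numeric(q_grid)
  d <- as.vector(stats::dist(sc$xyz))
  ii <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
  jj <- unlist(lapply(seq_len(n - 1), function(i) if (i < n) (i + 1):n))
  w <- sc$f[ii] * sc$f[jj]
  self_term <- sum(sc$f^2)
  intens <- vapply(q_grid, function(q) {
    if (q == 0) return(self_term + 2 * sum(w))
    qd <- q * d
    self_term + 2 * sum(w * sin(qd) / qd)
  }, numeric(1))
  saxs_profile(q_grid, intens, label = paste0("debye_", granularity))
}

#' Radius of gyration from coordinates
#'
#' Electron-count-weighted root-mean-square distance from the weighted
#' centroid, at the same granularity as [debye_profile()]. Serves as the
#' ground-truth oracle for Guinier estimates.
#'
#' @param model An [assembly()].
#' @param granularity `"residue"` (default) or `"atom"`.
#' @return Rg in Angstrom.
#' @export
rg_from_coordinates <- function(model, granularity = c("residue", "atom")) {
  sc <- scatterer_table(model, granularity)
  w <- sc$f / sum(sc$f)
  cen <- colSums(sc$xyz * w)
  sqrt(sum(w * rowSums(sweep(sc$xyz, 2, cen)^2)))
}

#' Guinier fit of the low-angle region
#'
#' Fits `ln I = ln I0 - q^2 Rg^2 / 3` by least squares on a low-q window
#' chosen deterministically: start from the 10 lowest-q points with positive
#' intensity, then grow the window one point at a time, refitting at each
#' step, while (i) `q_max * Rg` stays at or below `qrg_limit` and (ii) the
#' RMS log-space misfit stays below a threshold tied to the initial window
#' (three times its RMS, floored at 1e-4). The second guard stops the window
#' where the curve departs from the Guinier regime, so a compact body's Rg is
#' not biased by points near the validity limit, while noisy data still
#' extend to the full limit.
#'
#' @param profile A [saxs_profile()].
#' @param qrg_limit Upper limit on `q_max * Rg` (default 1.5).
#' @param n_start Number of points in the initial window (default 10,
#'   minimum 5).
#' @return A `guinier_fit` list: `I0`, `Rg` (Angstrom), `q_max_used`,
#'   `n_points`, `r_squared`.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.5, n_start = 10) {
  q <- profile$q; I <- profile$intensity
  if (n_start < 5) stop("need at least 5 points to start the Guinier window")
  usable <- which(I > 0)
  if (length(usable) < n_start) stop("fewer than ", n_start, " usable (positive) points")
  if (any(I[seq_len(min(n_start, length(I)))] <= 0)) {
    stop("non-positive intensities in the low-q Guinier window")
  }
  fit_window <- function(idx) {
    x <- q[idx]^2; y <- log(I[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) return(NULL)
    rg <- sqrt(-3 * slope)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    list(I0 = unname(exp(fit$coefficients[1])), Rg = unname(rg),
         r2 = unname(r2), rms = sqrt(mean(fit$residuals^2)))
  }
  idx <- usable[seq_len(n_start)]
  best <- fit_window(idx)
  if (is.null(best)) stop("Guinier fit failed on the initial window (non-negative slope)")
  rms_tol <- max(3 * best$rms, 1e-4)
  # shrink if the starting window already violates the limit
  while (q[idx[length(idx)]] * best$Rg > qrg_limit && length(idx) > 5) {
    idx <- idx[-length(idx)]
    cand <- fit_window(idx)
    if (is.null(cand)) stop("Guinier fit failed while shrinking the window")
    best <- cand
  }
  if (q[idx[length(idx)]] * best$Rg > qrg_limit) {
    stop("cannot satisfy the qRg limit with >= 5 points")
  }
  remaining <- usable[usable > idx[length(idx)]]
  for (nxt in remaining) {
    cand_idx <- c(idx, nxt)
    cand <- fit_window(cand_idx)
    if (is.null(cand) || q[nxt] * cand$Rg > qrg_limit || cand$rms > rms_tol) break
    idx <- cand_idx
    best <- cand
  }
  structure(
    list(I0 = best$I0, Rg = best$Rg, q_max_used = q[idx[length(idx)]],
         n_points = length(idx), r_squared = best$r2, qrg_limit = qrg_limit),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> Rg = %.2f A, I0 = %.4g, %d points, q_max = %.4f (qRg = %.2f), R^2 = %.4f\n",
              x$Rg, x$I0, x$n_points, x$q_max_used, x$q_max_used * x$Rg,
              x$r_squared))
  invisible(x)
}

#' Scale-optimal chi fit of an experimental profile against a model profile
#'
#' The theoretical curve is linearly interpolated onto the experimental grid
#' (no extrapolation) and scaled by the closed-form weighted least-squares
#' optimum `c`; the reported goodness of fit is
#' `chi = sqrt( sum(((I_exp - c I_model)/sigma)^2) / (N - 1) )`, with
#' `sigma = 1` when the experimental profile carries no uncertainties.
#'
#' @param experimental,theoretical [saxs_profile()] objects.
#' @return A `saxs_fit` list: `scale`, `chi`, `n`, `model_label`, and a
#'   `residuals` tibble (`q`, `residual`).
#' @export
chi_fit <- function(experimental, theoretical) {
  qe <- experimental$q
  keep <- qe >= min(theoretical$q) & qe <= max(theoretical$q)
  if (!any(keep)) stop("experimental and theoretical q ranges do not overlap")
  qe <- qe[keep]
  ie <- experimental$intensity[keep]
  sg <- if ("sigma" %in% names(experimental)) experimental$sigma[keep] else rep(1, length(qe))
  it <- stats::approx(theoretical$q, theoretical$intensity, xout = qe)$y
  scale <- sum(ie * it / sg^2) / sum(it^2 / sg^2)
  resid <- (ie - scale * it) / sg
  chi <- sqrt(sum(resid^2) / (length(resid) - 1))
  structure(
    list(scale = scale, chi = chi, n = length(resid),
         model_label = attr(theoretical, "label") %||% "model",
         residuals = tibble::tibble(q = qe, residual = resid)),
    class = "saxs_fit"
  )
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("<saxs_fit> model %s: chi = %.4g, scale = %.4g, n = %d\n",
              x$model_label, x$chi, x$scale, x$n))
  invisible(x)
}

#' Classify the oligomeric state of an experimental SAXS curve
#'
#' Computes a Debye profile for every candidate assembly on the experimental
#' q grid, chi-fits each, and calls the candidate with the minimum chi. When
#' a measured molecular mass and a subunit mass are supplied, the implied
#' subunit count `round(mass / subunit_mass)` is compared with the chain
#' count of the best candidate (the mass-consistency check used alongside
#' scattering shape in SEC-SAXS-MALS state assignment).
#'
#' @param experimental A [saxs_profile()].
#' @param candidates Named list of candidate [assembly()] models (at least 2).
#' @param measured_mass,subunit_mass Optional masses in kDa.
#' @param granularity Debye granularity (default `"residue"`).
#' @return An `oligomer_call` list: `best_model`, `chis` (named vector),
#'   `fits` (list of `saxs_fit`), `subunit_count`, `mass_consistent`.
#' @export
classify_oligomer <- function(experimental, candidates, measured_mass = NULL,
                              subunit_mass = NULL,
                              granularity = c("residue", "atom")) {
  granularity <- match.arg(granularity)
  if (length(candidates) < 2) stop("need at least 2 candidate models")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    stop("candidates must be a named list")
  }
  fits <- lapply(names(candidates), function(lb) {
    theo <- debye_profile(candidates[[lb]], experimental$q, granularity)
    attr(theo, "label") <- lb
    chi_fit(experimental, theo)
  })
  names(fits) <- names(candidates)
  chis <- vapply(fits, `[[`, numeric(1), "chi")
  best <- names(which.min(chis))
  subunit_count <- NA_integer_
  mass_consistent <- NA
  if (!is.null(measured_mass) && !is.null(subunit_mass)) {
    subunit_count <- as.integer(round(measured_mass / subunit_mass))
    mass_consistent <- length(assembly_chains(candidates[[best]])) == subunit_count
  }
  structure(
    list(best_model = best, chis = chis, fits = fits,
         subunit_count = subunit_count, mass_consistent = mass_consistent),
    class = "oligomer_call"
  )
}

#' @export
print.oligomer_call <- function(x, ...) {
  cat(sprintf("<oligomer_call> best model: %s\n", x$best_model))
  for (lb in names(x$chis)) {
    cat(sprintf("  %-12s chi = %.4g\n", lb, x$chis[lb]))
  }
  if (!is.na(x$subunit_count)) {
    cat(sprintf("  mass-implied subunits: %d (consistent with best model: %s)\n",
                x$subunit_count, x$mass_consistent))
  }
  invisible(x)
}

#' Merge SEC-SAXS frames with uniform Rg
#'
#' Uniform Rg across an elution peak indicates a homogeneous assembly; such
#' frames are merged to reduce noise. The maximal contiguous run of frames
#' whose Guinier Rg deviates at most `rg_tolerance` (fractional) from the
#' run median is retained and averaged pointwise, with uncertainties
#' propagated as the standard error of the mean.
#'
#' @param frames List of [saxs_profile()] objects on a common q grid (>= 2).
#' @param rg_tolerance Fractional Rg deviation allowed within a run
#'   (default 0.05).
#' @return A merged [saxs_profile()] with attributes `frames_used` (indices)
#'   and `frame_rg`.
#' @export
merge_frames <- function(frames, rg_tolerance = 0.05) {
  if (length(frames) < 2) stop("need at least 2 frames")
  q0 <- frames[[1]]$q
  same <- vapply(frames, function(f) {
    length(f$q) == length(q0) && all(abs(f$q - q0) < 1e-12)
  }, logical(1))
  if (!all(same)) stop("frames must share a common q grid")
  rgs <- vapply(frames, function(f) guinier_fit(f)$Rg, numeric(1))
  n <- length(frames)
  best_run <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      run <- i:j
      med <- stats::median(rgs[run])
      if (all(abs(rgs[run] - med) <= rg_tolerance * med)) {
        if (is.null(best_run) || length(run) > length(best_run)) best_run <- run
      }
    }
  }
  if (is.null(best_run)) stop("no contiguous run of >= 2 Rg-uniform frames")
  k <- length(best_run)
  im <- rowMeans(vapply(frames[best_run], function(f) f$intensity,
                        numeric(length(q0))))
  sg <- NULL
  if (all(vapply(frames[best_run], function(f) "sigma" %in% names(f), logical(1)))) {
    sg <- sqrt(rowSums(vapply(frames[best_run], function(f) f$sigma^2,
                              numeric(length(q0))))) / k
  }
  out <- saxs_profile(q0, im, sigma = sg, label = "merged")
  attr(out, "frames_used") <- best_run
  attr(out, "frame_rg") <- rgs
  out
}
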
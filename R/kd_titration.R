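# Equilibrium dissociation constants from fluorescence polarization.
#
# The labeled receptor (RAS loaded with a fluorescent non-hydrolysable GTP
# analog, held at R_t = 1 uM) is titrated with increasing total effector
# (ligand) concentrations E_t. Because R_t is not negligible relative to the
# K_d values of the tighter pairs, ligand depletion matters and the exact
# (tight-binding) solution of 1:1 mass action must be used: the complex
# concentration x is the physical root of
#     x^2 - (R_t + E_t + K_d) x + R_t E_t = 0,
# i.e. x = [(R_t+E_t+K_d) - sqrt((R_t+E_t+K_d)^2 - 4 R_t E_t)] / 2,
# and the polarization signal is linear in the bound fraction x / R_t.

#' Fraction of receptor bound under 1:1 mass action
#'
#' Exact tight-binding (quadratic) isotherm. The discriminant is clamped at
#' zero to guard against floating-point negatives near stoichiometric
#' binding.
#'
#' @param receptor_total Total receptor concentration R_t, uM (scalar > 0).
#' @param ligand_total Total ligand concentration(s) E_t, uM (>= 0,
#'   vectorized).
#' @param kd Dissociation constant, uM (>= 0).
#' @return Bound fraction(s) in `[0, min(1, E_t/R_t)]`.
#' @examples
#' fraction_bound(1, 0.5, 0)   # stoichiometric limit: 0.5
#' fraction_bound(1, 1, 1)     # (3 - sqrt(5)) / 2
#' @export
fraction_bound <- function(receptor_total, ligand_total, kd) {
  if (!is.numeric(receptor_total) || length(receptor_total) != 1 ||
      !is.finite(receptor_total) || receptor_total <= 0) {
    stop_raseff("receptor_total must be a single positive concentration", "domain")
  }
  if (any(!is.finite(ligand_total)) || any(ligand_total < 0)) {
    stop_raseff("ligand_total must be non-negative", "domain")
  }
  if (!is.numeric(kd) || length(kd) != 1 || !is.finite(kd) || kd < 0) {
    stop_raseff("kd must be a single non-negative concentration", "domain")
  }
  if (kd == 0) {
    # stoichiometric limit: the quadratic's discriminant is exactly
    # (R_t - E_t)^2 but loses that identity in floating point, so use the
    # closed form directly
    return(pmin(ligand_total, receptor_total) / receptor_total)
  }
  b <- receptor_total + ligand_total + kd
  disc <- b^2 - 4 * receptor_total * ligand_total
  disc[disc < 0] <- 0
  x <- (b - sqrt(disc)) / 2
  x / receptor_total
}

#' Construct a titration curve
#'
#' @param ligand_totals Strictly increasing effector concentrations, uM.
#' @param signals Polarization values (arbitrary units), or `NULL` for a bare
#'   design.
#' @param receptor_total Fixed labeled-receptor concentration, uM (default 1).
#' @param ras,effector Optional pair labels.
#' @return Tibble of class `titration_curve` with columns `ligand_total` and
#'   (if given) `signal`; receptor concentration and labels are attributes.
#' @export
titration_curve <- function(ligand_totals, signals = NULL, receptor_total = 1,
                            ras = NA_character_, effector = NA_character_) {
  if (any(ligand_totals < 0) || is.unsorted(ligand_totals, strictly = TRUE)) {
    stop_raseff("ligand_totals must be non-negative and strictly increasing", "domain")
  }
  if (receptor_total <= 0) stop_raseff("receptor_total must be positive", "domain")
  if (!is.null(signals) && length(signals) != length(ligand_totals)) {
    stop_raseff("signals must match ligand_totals in length", "domain")
  }
  out <- tibble(ligand_total = as.double(ligand_totals))
  if (!is.null(signals)) out$signal <- as.double(signals)
  attr(out, "receptor_total") <- receptor_total
  attr(out, "meta") <- list(ras = ras, effector = effector)
  class(out) <- c("titration_curve", class(out))
  out
}

#' Log-spaced titration design
#'
#' The default design mirrors the experimental span: 24 log-spaced effector
#' concentrations from 0.05 to 100 uM titrated into 1 uM labeled receptor.
#'
#' @param n_points Number of concentrations (default 24).
#' @param conc_range Span `(min, max)` in uM (default `c(0.05, 100)`).
#' @inheritParams titration_curve
#' @return A `titration_curve` without signals.
#' @export
titration_design <- function(n_points = 24, conc_range = c(0.05, 100),
                             receptor_total = 1, ras = NA_character_,
                             effector = NA_character_) {
  if (length(conc_range) != 2 || any(conc_range <= 0) || diff(conc_range) <= 0) {
    stop_raseff("conc_range must be positive and increasing", "domain")
  }
  e <- exp(seq(log(conc_range[1]), log(conc_range[2]), length.out = n_points))
  titration_curve(e, receptor_total = receptor_total, ras = ras, effector = effector)
}

#' Model polarization signal for a design
#'
#' `P(E_t) = p_free + (p_bound - p_free) * fraction_bound(R_t, E_t, kd)`.
#'
#' @param design A `titration_curve` (signals ignored if present).
#' @param kd Dissociation constant, uM.
#' @param p_free Signal of the free receptor.
#' @param p_bound Signal at full saturation.
#' @return Numeric vector of signals.
#' @export
model_signal <- function(design, kd, p_free, p_bound) {
  rt <- attr(design, "receptor_total") %||% 1
  p_free + (p_bound - p_free) * fraction_bound(rt, design$ligand_total, kd)
}

#' Fit the quadratic binding isotherm to a titration
#'
#' Unit-weight least squares over (K_d, P_free, P_bound) with K_d kept
#' positive through a log parameterization. Starting values: P_free = first
#' signal, P_bound = last signal, K_d = the ligand concentration at the
#' half-signal point (log-interpolated). The standard error of K_d is
#' obtained from the Jacobian at the optimum via the delta method on log K_d.
#'
#' @param curve A `titration_curve` with at least 5 points and non-constant
#'   signals.
#' @return Object of class `binding_fit`: list with `kd`, `p_free`,
#'   `p_bound`, `residual_norm` (sum of squared residuals), `stderr_kd`,
#'   `converged`, `meta`, `curve` and the underlying `nls` fit.
#' @examples
#' des <- titration_design()
#' cur <- titration_curve(des$ligand_total, model_signal(des, 0.5, 0, 1))
#' fit <- fit_titration(cur)
#' fit$kd
#' @export
fit_titration <- function(curve) {
  if (!"signal" %in% names(curve)) {
    stop_raseff("curve carries no signals", "insufficient_data")
  }
  if (nrow(curve) < 5) {
    stop_raseff("at least 5 titration points are required", "insufficient_data")
  }
  s <- curve$signal
  e <- curve$ligand_total
  rt <- attr(curve, "receptor_total") %||% 1
  if (diff(range(s)) == 0) {
    stop_raseff("signals are constant; binding curve is degenerate", "degenerate_data")
  }

  p_free0 <- s[1]
  p_bound0 <- s[length(s)]
  s_half <- (p_free0 + p_bound0) / 2
  # log-interpolated concentration at half signal; fall back to the median
  kd0 <- tryCatch({
    ord <- order(s)
    a <- approx(s[ord], log(e[ord]), xout = s_half, ties = mean)$y
    if (is.na(a)) median(e) else exp(a)
  }, error = function(e2) median(e))
  kd0 <- max(kd0, 1e-6)

  dat <- data.frame(e = e, s = s)
  # deterministic ladder of start-value perturbations: with noise-free data a
  # machine-perfect optimum can make the post-hoc gradient matrix singular,
  # which a slightly different approach path avoids
  starts <- list(
    list(log_kd = log(kd0), p_free = p_free0, p_bound = p_bound0),
    list(log_kd = log(kd0 * 2), p_free = p_free0, p_bound = p_bound0),
    list(log_kd = log(kd0 / 2), p_free = p_free0, p_bound = p_bound0),
    list(log_kd = log(kd0), p_free = p_free0,
         p_bound = p_bound0 + 0.05 * (p_bound0 - p_free0)),
    list(log_kd = log(median(e)), p_free = min(s), p_bound = max(s))
  )
  fit <- NULL
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        s ~ p_free + (p_bound - p_free) * fraction_bound(rt, e, exp(log_kd)),
        data = dat, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(err) { last_err <<- err; NULL }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop_raseff(paste0("nonlinear least squares failed: ",
                       conditionMessage(last_err)), "fit_failed")
  }
  cf <- coef(fit)
  kd <- exp(cf[["log_kd"]])
  se_log <- tryCatch(sqrt(diag(vcov(fit)))[["log_kd"]], error = function(e2) NA_real_)
  conv_info <- fit$convInfo
  structure(list(
    kd = kd,
    p_free = cf[["p_free"]],
    p_bound = cf[["p_bound"]],
    residual_norm = sum(stats::residuals(fit)^2),
    stderr_kd = kd * se_log,  # delta method on log K_d
    converged = isTRUE(conv_info$isConv) ||
      (!is.null(conv_info$stopCode) && conv_info$stopCode %in% 1:4),
    receptor_total = rt,
    meta = attr(curve, "meta"),
    curve = curve,
    fit = fit
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit: K_d = %.4g uM (SE %.2g), P_free = %.3g, P_bound = %.3g, SSR = %.3g%s>\n",
              x$kd, x$stderr_kd, x$p_free, x$p_bound, x$residual_norm,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Tidy a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`kd`, `p_free`, `p_bound`),
#'   columns `term`, `estimate`, `std.error`.
#' @export
tidy.binding_fit <- function(x, ...) {
  se <- tryCatch(sqrt(diag(vcov(x$fit))), error = function(e) rep(NA_real_, 3))
  tibble(
    term = c("kd", "p_free", "p_bound"),
    estimate = c(x$kd, x$p_free, x$p_bound),
    std.error = c(x$stderr_kd, se[["p_free"]], se[["p_bound"]])
  )
}

#' One-row summary of a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return One-row tibble with `kd`, `stderr_kd`, `p_free`, `p_bound`,
#'   `residual_norm`, `converged`, `n`.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(kd = x$kd, stderr_kd = x$stderr_kd, p_free = x$p_free,
         p_bound = x$p_bound, residual_norm = x$residual_norm,
         converged = x$converged, n = nrow(x$curve))
}

#' Plot a titration and its fitted isotherm
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot object (log-scaled concentration axis).
#' @export
autoplot.binding_fit <- function(object, ...) {
  cur <- object$curve
  grid <- exp(seq(log(min(cur$ligand_total)), log(max(cur$ligand_total)),
                  length.out = 200))
  pred <- tibble(
    ligand_total = grid,
    signal = object$p_free + (object$p_bound - object$p_free) *
      fraction_bound(object$receptor_total, grid, object$kd)
  )
  ggplot2::ggplot(cur, ggplot2::aes(x = .data$ligand_total, y = .data$signal)) +
    ggplot2::geom_line(data = pred, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "effector total (uM)", y = "polarization (a.u.)",
                  title = sprintf("K_d = %.3g uM", object$kd)) +
    ggplot2::theme_minimal()
}

#' Mean and standard error over replicate fits
#'
#' @param fits List of `binding_fit` objects (or a numeric vector of K_d
#'   values) for replicates of the same pair.
#' @return One-row tibble with `mean_kd`, `sem_kd`, `n`.
#' @export
replicate_summary <- function(fits) {
  kds <- if (is.numeric(fits)) fits else {
    vapply(fits, function(f) f$kd, double(1))
  }
  if (length(kds) < 2) {
    stop_raseff("at least 2 replicate fits are required", "insufficient_replicates")
  }
  tibble(mean_kd = mean(kds), sem_kd = sd(kds) / sqrt(length(kds)),
         n = length(kds))
}

#' Read a titration table from TSV
#'
#' Expects columns `ligand_total_uM` (or `ligand_total_nM`) and
#' `polarization`.
#'
#' @param path File path.
#' @inheritParams titration_curve
#' @return A `titration_curve`.
#' @export
read_titration_tsv <- function(path, receptor_total = 1,
                               ras = NA_character_, effector = NA_character_) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if ("ligand_total_uM" %in% names(tab)) {
    e <- tab$ligand_total_uM
  } else if ("ligand_total_nM" %in% names(tab)) {
    e <- tab$ligand_total_nM / 1000
  } else {
    stop_raseff(sprintf("no ligand_total_uM/ligand_total_nM column in '%s'", path),
                "malformed_input")
  }
  if (!"polarization" %in% names(tab)) {
    stop_raseff(sprintf("no polarization column in '%s'", path), "malformed_input")
  }
  titration_curve(e, tab$polarization, receptor_total = receptor_total,
                  ras = ras, effector = effector)
}

#' Published reference dissociation constants
#'
#' The 25 equilibrium dissociation constants (uM) measured by fluorescence
#' polarization under uniform conditions for five RAS-family GTPases (HRAS,
#' KRAS, NRAS, RRAS1, RRAS2) against five effector RB/RA domains. Used as
#' ground-truth inputs for synthetic recovery studies and as the canonical
#' row/column ordering of affinity tables.
#'
#' @return Tibble with columns `effector`, `ras`, `kd_um` (25 rows).
#' @export
reference_kd_table <- function() {
  effector_names <- c("CRAF-RB", "RASSF5-RA", "RALGDS-RA", "PLCe-RA2", "PI3Ka-RB")
  ras_names <- c("HRAS", "KRAS", "NRAS", "RRAS1", "RRAS2")
  kd <- c(
    0.094, 0.142, 0.048, 2.29, 4.09,    # CRAF-RB
    0.238, 0.421, 0.442, 11.5, 10.00,   # RASSF5-RA
    2.50, 1.39, 2.84, 9.71, 5.78,       # RALGDS-RA
    3.70, 8.90, 5.36, 114.4, 145.4,     # PLCe-RA2
    84.3, 204.7, 145.0, 11.00, 18.10    # PI3Ka-RB
  )
  tibble(
    effector = rep(effector_names, each = length(ras_names)),
    ras = rep(ras_names, times = length(effector_names)),
    kd_um = kd
  )
}
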
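#' Titration calorimetry experiment geometry
#'
#' Concentrations and volumes describing one ITC titration: macromolecule
#' (arrestin) in the cell, ligand (phosphopeptide) in the syringe,
#' injected in fixed small volumes at constant temperature. Defaults follow
#' the standard small-cell instrument setup: a 200 uL cell with 200 uM
#' macromolecule titrated by 25 injections of 2.5 uL of 1000 uM peptide at
#' 298 K.
#'
#' @param cell_volume_uL active cell volume in uL
#' @param macromolecule_uM initial cell (macromolecule) concentration in uM
#' @param syringe_uM syringe (injectant) concentration in uM
#' @param injection_volumes_uL vector of per-injection volumes in uL
#' @param temperature_K temperature in K
#' @return object of class `itc_experiment`
#' @export
itc_experiment <- function(cell_volume_uL = 200, macromolecule_uM = 200,
                           syringe_uM = 1000,
                           injection_volumes_uL = rep(2.5, 25),
                           temperature_K = 298) {
  if (cell_volume_uL <= 0 || macromolecule_uM <= 0 || syringe_uM < 0 ||
      any(injection_volumes_uL <= 0) || temperature_K <= 0)
    stop("cell volume, concentrations, injection volumes and temperature must be positive")
  structure(list(cell_volume_uL = cell_volume_uL,
                 macromolecule_uM = macromolecule_uM,
                 syringe_uM = syringe_uM,
                 injection_volumes_uL = injection_volumes_uL,
                 temperature_K = temperature_K),
            class = "itc_experiment")
}

#' Binding parameters for one or two independent site classes
#'
#' Two-site here means two INDEPENDENT classes of sites on the
#' macromolecule, each with its own dissociation constant and enthalpy —
#' the model behind a biphasic isotherm where a high-affinity site I fills
#' at low molar ratio and a low-affinity site II only at higher ratios.
#' When both sites are present the convention kd1 <= kd2 (site I = high
#' affinity) is enforced by reordering.
#'
#' @param kd1 dissociation constant of site I in uM (> 0)
#' @param kd2 dissociation constant of site II in uM, or `NULL` for one-site
#' @param dh1,dh2 enthalpies in kcal per mol of injectant
#' @param n1,n2 site stoichiometries (default 1)
#' @param baseline heat offset in kcal/mol applied to every injection
#' @return object of class `binding_params`
#' @export
binding_params <- function(kd1, dh1, kd2 = NULL, dh2 = NULL,
                           n1 = 1.0, n2 = 1.0, baseline = 0.0) {
  two_site <- !is.null(kd2)
  if (two_site && is.null(dh2)) stop("two-site parameters require dh2")
  if (kd1 <= 0 || (two_site && kd2 <= 0)) stop("kd must be > 0")
  if (two_site && kd2 < kd1) {  # enforce site I = high affinity
    tmp <- kd1; kd1 <- kd2; kd2 <- tmp
    tmp <- dh1; dh1 <- dh2; dh2 <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  structure(list(kd1 = kd1, kd2 = if (two_site) kd2 else NULL,
                 dh1 = dh1, dh2 = if (two_site) dh2 else NULL,
                 n1 = n1, n2 = if (two_site) n2 else NULL,
                 baseline = baseline,
                 model = if (two_site) "two_site" else "one_site"),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  if (x$model == "two_site")
    cat(sprintf(
      "<binding_params two-site> kd1 = %.3g uM, kd2 = %.3g uM, dh1 = %.3g, dh2 = %.3g kcal/mol (n1 = %.2f, n2 = %.2f)\n",
      x$kd1, x$kd2, x$dh1, x$dh2, x$n1, x$n2))
  else
    cat(sprintf("<binding_params one-site> kd = %.3g uM, dh = %.3g kcal/mol (n = %.2f)\n",
                x$kd1, x$dh1, x$n1))
  invisible(x)
}

# Vectorised bracketed bisection for the free-ligand mass balance:
#   L + M * (n1*L/(kd1+L) + n2*L/(kd2+L)) = L_total
# The left side is strictly increasing in L, so [0, L_total] brackets the
# unique root; 80 halvings reach well below 1e-12 relative tolerance.
free_ligand_bisect <- function(l_total, m_total, params) {
  stopifnot(length(l_total) == length(m_total))
  bound <- function(L) {
    b <- params$n1 * L / (params$kd1 + L)
    if (!is.null(params$kd2)) b <- b + params$n2 * L / (params$kd2 + L)
    m_total * b
  }
  lo <- rep(0, length(l_total))
  hi <- l_total
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    too_high <- mid + bound(mid) > l_total
    hi[too_high] <- mid[too_high]
    lo[!too_high] <- mid[!too_high]
  }
  (lo + hi) / 2
}

#' Solve the free-ligand concentration
#'
#' Root of the mass balance L + M * sum_s n_s L/(kd_s + L) = L_total by
#' bracketed bisection on [0, L_total] to a relative tolerance of 1e-12.
#'
#' @param total_ligand total ligand concentration in uM (>= 0)
#' @param total_macromolecule total macromolecule concentration in uM (>= 0)
#' @param params a [binding_params()]
#' @return free ligand concentration in uM
#' @export
free_ligand_solve <- function(total_ligand, total_macromolecule, params) {
  stopifnot(inherits(params, "binding_params"))
  if (any(total_ligand < 0) || any(total_macromolecule < 0))
    stop("concentrations must be non-negative")
  n <- max(length(total_ligand), length(total_macromolecule))
  free_ligand_bisect(rep_len(total_ligand, n),
                     rep_len(total_macromolecule, n), params)
}

#' Simulate a binding isotherm
#'
#' Forward model of the injection-heat table. Each injection of volume v
#' into a cell of volume V0 displaces cell content: prior totals are diluted
#' by (1 - v/V0) and ligand is added at the syringe concentration times
#' v/V0. The cumulative heat content after injection i is
#' Q_i = V0 * M_i * (n1 theta1 dh1 + n2 theta2 dh2) with site occupancies
#' theta_s = L_free/(kd_s + L_free). The reported per-injection heat applies
#' the displaced-volume correction and is normalised per mole of injectant
#' (Wiseman presentation):
#' heat_i = (Q_i - Q_{i-1} + (v_i/V0) (Q_i + Q_{i-1})/2) / mol_injected + baseline.
#'
#' @param exp an [itc_experiment()]
#' @param params a [binding_params()]
#' @return object of class `isotherm`: data.frame with `injection`,
#'   `volume_uL`, `molar_ratio`, `heat_kcal_per_mol`
#' @export
simulate_isotherm <- function(exp, params) {
  stopifnot(inherits(exp, "itc_experiment"), inherits(params, "binding_params"))
  v0 <- exp$cell_volume_uL
  vols <- exp$injection_volumes_uL
  ninj <- length(vols)
  m_tot <- l_tot <- numeric(ninj)
  m <- exp$macromolecule_uM
  l <- 0
  for (i in seq_len(ninj)) {
    f <- 1 - vols[i] / v0
    m <- m * f
    l <- l * f + exp$syringe_uM * vols[i] / v0
    m_tot[i] <- m
    l_tot[i] <- l
  }
  lf <- free_ligand_bisect(l_tot, m_tot, params)
  occ <- params$n1 * lf / (params$kd1 + lf)
  if (!is.null(params$kd2)) {
    q <- v0 * 1e-6 * m_tot * 1e-6 *
      (occ * params$dh1 + params$n2 * lf / (params$kd2 + lf) * params$dh2)
  } else {
    q <- v0 * 1e-6 * m_tot * 1e-6 * occ * params$dh1
  }
  q_prev <- c(0, q[-ninj])
  mol_inj <- exp$syringe_uM * 1e-6 * vols * 1e-6
  if (exp$syringe_uM == 0) {  # nothing injected: baseline-only heats
    heat <- rep(params$baseline, ninj)
  } else {
    heat <- (q - q_prev + (vols / v0) * (q + q_prev) / 2) / mol_inj +
      params$baseline
  }
  out <- data.frame(injection = seq_len(ninj), volume_uL = vols,
                    molar_ratio = l_tot / m_tot, heat_kcal_per_mol = heat)
  class(out) <- c("isotherm", "data.frame")
  out
}

#' Read an isotherm injection table
#'
#' Expected CSV columns: `injection`, `volume_uL`, `heat_kcal_per_mol`
#' (or `heat_ucal` plus `syringe_uM`-based conversion via `ucal = TRUE`).
#'
#' @param path CSV file path
#' @param ucal if `TRUE` the heat column is `heat_ucal` (raw microcalories
#'   per injection) and is converted to kcal per mol of injectant using
#'   `syringe_uM`
#' @param syringe_uM syringe concentration, required when `ucal = TRUE`
#' @return an `isotherm` data.frame
#' @export
read_isotherm_csv <- function(path, ucal = FALSE, syringe_uM = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("injection", "volume_uL",
            if (ucal) "heat_ucal" else "heat_kcal_per_mol")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop(sprintf("isotherm table is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  if (ucal) {
    if (is.null(syringe_uM)) stop("ucal conversion requires syringe_uM")
    mol_inj <- syringe_uM * 1e-6 * df$volume_uL * 1e-6
    df$heat_kcal_per_mol <- df$heat_ucal * 1e-9 / mol_inj
  }
  if (!"molar_ratio" %in% names(df)) df$molar_ratio <- NA_real_
  out <- df[, c("injection", "volume_uL", "molar_ratio", "heat_kcal_per_mol")]
  class(out) <- c("isotherm", "data.frame")
  out
}

itc_pack <- function(params) {
  if (params$model == "two_site")
    c(log_kd1 = log(params$kd1), log_kd2 = log(params$kd2),
      dh1 = params$dh1, dh2 = params$dh2, baseline = params$baseline)
  else
    c(log_kd1 = log(params$kd1), dh1 = params$dh1, baseline = params$baseline)
}

itc_unpack <- function(par, model) {
  if (model == "two_site")
    binding_params(kd1 = exp(par[["log_kd1"]]), dh1 = par[["dh1"]],
                   kd2 = exp(par[["log_kd2"]]), dh2 = par[["dh2"]],
                   baseline = par[["baseline"]])
  else
    binding_params(kd1 = exp(par[["log_kd1"]]), dh1 = par[["dh1"]],
                   baseline = par[["baseline"]])
}

# Initial guesses: kd from the molar ratio at the steepest descent of the
# (smoothed) isotherm per phase, dh from plateau heights.
itc_init <- function(iso, exp, model) {
  h <- iso$heat_kcal_per_mol
  m_cell <- exp$macromolecule_uM
  # steepest-descent injection marks the transition of the dominant phase;
  # a later transition (relative to the titration length) means weaker
  # binding, so scale the kd guess up with its position
  drop_frac <- which.min(diff(h)) / length(h)
  kd1 <- m_cell / 50 * max(1, 10 * drop_frac)
  dh1 <- h[1]
  if (model == "two_site")
    binding_params(kd1 = kd1, dh1 = dh1, kd2 = m_cell / 5,
                   dh2 = stats::median(h), baseline = 0)
  else
    binding_params(kd1 = kd1, dh1 = dh1, baseline = 0)
}

#' Fit a binding isotherm
#'
#' Nonlinear least squares of the [simulate_isotherm()] forward model
#' against observed injection heats (Levenberg-Marquardt), with
#' multi-start initialisation: dissociation constants are jittered
#' geometrically (x/÷ 3, and wider) around the heuristic start because
#' biphasic curves have local minima. Stoichiometries are held at 1 per
#' site class. Two-site results are reported with kd1 <= kd2.
#'
#' @param iso an `isotherm` (observed heats)
#' @param exp the [itc_experiment()] that produced it
#' @param model `"one_site"` or `"two_site"`
#' @param n_starts number of multi-start initialisations (default 8)
#' @return object of class `itc_fit`: `params` ([binding_params()]), `ssr`,
#'   `converged`, `model`, `fitted` heats, `n_obs`, `n_par`
#' @export
fit_isotherm <- function(iso, exp, model = c("two_site", "one_site"),
                         n_starts = 8L) {
  model <- match.arg(model)
  obs <- iso$heat_kcal_per_mol
  n_par <- if (model == "two_site") 5L else 3L
  if (length(obs) < 2L * n_par)
    stop(sprintf("need at least %d injections to fit %d parameters",
                 2L * n_par, n_par))
  resid_fn <- function(par) {
    p <- itc_unpack_raw(par, model)
    simulate_isotherm(exp, p)$heat_kcal_per_mol - obs
  }
  init <- itc_init(iso, exp, model)
  base_par <- itc_pack(init)
  # constrain kd to the identifiable window of this titration: beyond
  # ~10x the final total ligand the heats carry no curvature information
  # and the optimiser can wander into a quasi-linear degenerate basin
  kd_upper <- itc_kd_bound(exp)
  lower <- rep(-Inf, length(base_par))
  upper <- rep(Inf, length(base_par))
  kd_idx <- grep("^log_kd", names(base_par))
  lower[kd_idx] <- log(1e-6)
  upper[kd_idx] <- log(kd_upper)
  base_par[kd_idx] <- pmin(base_par[kd_idx], log(kd_upper) - 0.5)
  jitters <- exp_grid(n_starts)
  best <- NULL
  for (j in seq_len(nrow(jitters))) {
    par0 <- base_par
    par0[["log_kd1"]] <- par0[["log_kd1"]] + jitters[j, 1]
    if (model == "two_site")
      par0[["log_kd2"]] <- par0[["log_kd2"]] + jitters[j, 2]
    par0[kd_idx] <- pmin(pmax(par0[kd_idx], lower[kd_idx]), upper[kd_idx])
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(fit = fit, ssr = ssr,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best)) stop("all optimisation starts failed")
  params <- itc_unpack_raw(coef(best$fit), model)  # reorders kd1 <= kd2
  structure(list(params = params, ssr = best$ssr,
                 converged = best$converged, model = model,
                 fitted = simulate_isotherm(exp, params)$heat_kcal_per_mol,
                 n_obs = length(obs), n_par = n_par),
            class = "itc_fit")
}

# identifiable kd window: a multiple of the final total ligand concentration
itc_kd_bound <- function(exp, mult = 10) {
  l_final <- exp$syringe_uM *
    (1 - prod(1 - exp$injection_volumes_uL / exp$cell_volume_uL))
  mult * l_final
}

# unpack that tolerates unordered kds during optimisation
itc_unpack_raw <- function(par, model) {
  par <- stats::setNames(as.numeric(par), names(par))
  itc_unpack(par, model)
}

# symmetric multiplicative jitter grid on log-kd (units: log(3))
exp_grid <- function(n) {
  steps <- log(3) * c(0, -1, 1, -2, 2, -3, 3, 0)
  g <- cbind(steps, rev(steps))
  g[rep_len(seq_len(nrow(g)), n), , drop = FALSE]
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("<itc_fit %s> ssr = %.4g, converged = %s\n", x$model, x$ssr,
              x$converged))
  print(x$params)
  invisible(x)
}

# Per-site heat signal of a fitted model: |dh_k| times the swing of site
# k's fractional occupancy across the titration — the amplitude that site
# actually contributes to the observed heats.
itc_site_signals <- function(fit, exp) {
  params <- fit$params
  v0 <- exp$cell_volume_uL
  vols <- exp$injection_volumes_uL
  m <- exp$macromolecule_uM; l <- 0
  m_tot <- l_tot <- numeric(length(vols))
  for (i in seq_along(vols)) {
    f <- 1 - vols[i] / v0
    m <- m * f; l <- l * f + exp$syringe_uM * vols[i] / v0
    m_tot[i] <- m; l_tot[i] <- l
  }
  lf <- free_ligand_bisect(l_tot, m_tot, params)
  th1 <- c(0, lf / (params$kd1 + lf))
  sig <- c(dh1 = abs(params$dh1) * (max(th1) - min(th1)))
  if (!is.null(params$kd2)) {
    th2 <- c(0, lf / (params$kd2 + lf))
    sig <- c(sig, dh2 = abs(params$dh2) * (max(th2) - min(th2)))
  }
  sig
}

#' Compare one-site and two-site isotherm fits
#'
#' Extra-sum-of-squares F test of the two-site model (2 extra parameters)
#' against the nested one-site model. The two-site model is preferred only
#' if three conditions hold:
#' * the F test is significant at `alpha`;
#' * both sites' heat signals exceed the noise floor — the signal of site k
#'   is `|dh_k|` scaled by the swing of that site's fractional occupancy
#'   over the titration, and the floor is `floor_mult` times the residual
#'   standard deviation (a site whose contribution is invisible in the
#'   heats cannot be claimed);
#' * both dissociation constants lie within the titrated concentration
#'   range (`kd <= kd_range_mult` times the final total ligand): a kd far
#'   beyond the titrated range is pure extrapolation — the classic
#'   degenerate fit there is a quasi-linear pseudo-site with an enormous
#'   compensating enthalpy.
#'
#' Baseline-only data is flagged as "no binding".
#'
#' @param iso an `isotherm`
#' @param exp the [itc_experiment()]
#' @param alpha F-test significance level (default 0.05)
#' @param floor_mult noise-floor multiplier on the residual SD (default 3)
#' @param kd_range_mult identifiability bound on kd as a multiple of the
#'   final total ligand concentration (default 10)
#' @return list: `preferred` ("one_site"/"two_site"), `f_stat`, `p_value`,
#'   `site_signals` (two-site per-site heat amplitudes, kcal/mol),
#'   `noise_floor`, `kd_bound_uM`, `fit_one`, `fit_two`, `no_binding`
#' @export
compare_models <- function(iso, exp, alpha = 0.05, floor_mult = 3,
                           kd_range_mult = 10) {
  fit1 <- fit_isotherm(iso, exp, "one_site")
  fit2 <- fit_isotherm(iso, exp, "two_site")
  n <- fit2$n_obs
  df2 <- n - fit2$n_par
  f_stat <- ((fit1$ssr - fit2$ssr) / 2) / (fit2$ssr / df2)
  f_stat <- max(0, f_stat)
  p_value <- stats::pf(f_stat, 2, df2, lower.tail = FALSE)
  floor <- floor_mult * sqrt(fit2$ssr / df2)
  sig <- itc_site_signals(fit2, exp)
  kd_bound <- itc_kd_bound(exp, kd_range_mult)
  # strict: a kd sitting on the fit's own box bound is a boundary artefact
  kds_identifiable <- max(fit2$params$kd1, fit2$params$kd2) < 0.99 * kd_bound
  preferred <- if (p_value < alpha && all(sig > floor) && kds_identifiable)
    "two_site" else "one_site"
  sig1 <- itc_site_signals(fit1, exp)
  no_binding <- sig1[["dh1"]] <= floor_mult * sqrt(fit1$ssr / (n - fit1$n_par))
  list(preferred = preferred, f_stat = f_stat, p_value = p_value,
       site_signals = sig, noise_floor = floor, kd_bound_uM = kd_bound,
       fit_one = fit1, fit_two = fit2, no_binding = no_binding)
}
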
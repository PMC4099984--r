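# biokinetics: linear compartmental models and cumulated activities.
#
# A model is the linear system dA/dt = K A - lambda_p A with K the biological
# transfer-rate matrix (per day, K[i,j] = rate j->i for i != j, diagonal =
# minus the column outflow) and lambda_p the physical decay constant. The
# cumulated activity per unit administered activity is the time integral
# A~ = \int_0^inf A(t) dt = (lambda_p I - K)^{-1} A0, solved directly; ODE
# integration is kept only as an independent oracle in the tests. When every
# excretion route is an explicit compartment, sum(A~) * lambda_p = 1 exactly:
# each administered atom decays exactly once, somewhere.

#' Construct a linear compartmental biokinetic model
#'
#' @param compartments character vector of compartment names.
#' @param transfers data.frame with columns \code{from}, \code{to},
#'   \code{rate} (biological transfer rates, per day). All sinks must be
#'   explicit compartments: there is no implicit loss term.
#' @param lambda_phys physical decay constant, per day.
#' @param A0 named initial activity distribution per unit administered
#'   (entries >= 0, summing to 1); names are compartments.
#' @param region_map named character vector mapping compartments to source
#'   regions (many-to-one).
#' @param excreta character vector of compartments that are excreta sinks.
#' @return object of class \code{compartment_model}.
#' @export
compartment_model <- function(compartments, transfers, lambda_phys, A0,
                              region_map = NULL, excreta = character(0)) {
  stopifnot(lambda_phys > 0, !anyDuplicated(compartments))
  n <- length(compartments)
  K <- matrix(0, n, n, dimnames = list(compartments, compartments))
  if (nrow(transfers)) {
    stopifnot(all(transfers$from %in% compartments),
              all(transfers$to %in% compartments),
              all(transfers$rate >= 0))
    for (r in seq_len(nrow(transfers)))
      K[transfers$to[r], transfers$from[r]] <-
        K[transfers$to[r], transfers$from[r]] + transfers$rate[r]
  }
  diag(K) <- -colSums(K)
  a0 <- setNames(numeric(n), compartments)
  a0[names(A0)] <- A0
  stopifnot(all(a0 >= 0), abs(sum(a0) - 1) < 1e-9)
  if (is.null(region_map)) region_map <- setNames(compartments, compartments)
  stopifnot(all(compartments %in% names(region_map)))
  structure(list(compartments = compartments, K = K, transfers = transfers,
                 lambda_phys = lambda_phys, A0 = a0,
                 region_map = region_map, excreta = excreta),
            class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf("compartment_model: %d compartments, %d transfers, lambda_p = %.5g /d (T1/2 = %.4g h)\n",
              length(x$compartments), nrow(x$transfers), x$lambda_phys,
              24 * log(2) / x$lambda_phys))
  invisible(x)
}

#' Cumulated activities of a compartmental model
#'
#' Solves \eqn{(\lambda_p I - K) \tilde A = A_0} and sums compartments into
#' source regions. Units: hours per unit administered activity (MBq h/MBq).
#'
#' @param model a \code{compartment_model}.
#' @return object of class \code{cumulated_activity_set} with fields
#'   \code{entries} (named region vector, hours), \code{compartment_hours},
#'   \code{provenance = "computed"}, \code{nuclide}, \code{uptake}.
#' @export
cumulated_activities <- function(model) {
  n <- length(model$compartments)
  M <- diag(model$lambda_phys, n) - model$K
  if (abs(det(M)) < 1e-300) stop("singular biokinetic system")  # cannot occur for lambda_p > 0
  tilde_days <- solve(M, model$A0)
  hrs <- 24 * setNames(as.numeric(tilde_days), model$compartments)
  regions <- model$region_map[model$compartments]
  entries <- tapply(hrs, regions, sum)
  cumulated_activity_set(entries = entries,
                         nuclide = attr(model, "nuclide") %||% NA_character_,
                         uptake = attr(model, "uptake") %||% NA_real_,
                         provenance = "computed",
                         compartment_hours = hrs)
}

#' Container for cumulated activities per source region
#'
#' @param entries named numeric vector, region -> cumulated activity in hours
#'   per unit administered activity.
#' @param nuclide,uptake,provenance metadata (\code{provenance} is one of
#'   \code{"computed"}, \code{"russell"}, \code{"icrp53"}).
#' @param compartment_hours optional per-compartment breakdown.
#' @return object of class \code{cumulated_activity_set}.
#' @export
cumulated_activity_set <- function(entries, nuclide = NA_character_,
                                   uptake = NA_real_,
                                   provenance = "computed",
                                   compartment_hours = NULL) {
  e <- setNames(as.numeric(entries), names(entries))
  stopifnot(all(e >= -1e-12))
  structure(list(nuclide = nuclide, uptake = uptake, provenance = provenance,
                 entries = e, compartment_hours = compartment_hours),
            class = "cumulated_activity_set")
}

#' @export
print.cumulated_activity_set <- function(x, ...) {
  cat(sprintf("cumulated_activity_set [%s] nuclide=%s uptake=%s\n",
              x$provenance, x$nuclide,
              if (is.na(x$uptake)) "-" else paste0(100 * x$uptake, "%")))
  for (r in names(x$entries))
    cat(sprintf("  %-28s %10.4f h\n", r, x$entries[r]))
  invisible(x)
}

#' Canonical maximum-thyroid-uptake levels
#'
#' The six conventional diagnostic levels 5--55\% plus the extreme 95\% level
#' covering hyperthyroid patients.
#' @return numeric vector of uptake fractions.
#' @export
uptake_levels <- function() c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55, 0.95)

#' Default rate constants for the iodide-in-pregnancy model
#'
#' The model structure (which compartments exchange with which) is fixed by
#' \code{\link{build_iodide_pregnancy_model}}; the numeric transfer constants
#' are an editable bundle. The published compartmental treatments of iodide
#' in pregnancy do not print their rate constants, so the defaults here are
#' package choices: conventional iodide kinetics (fast blood clearance split
#' between thyroid trapping and renal excretion, salivary/gastric recycling,
#' slow release of organically bound iodine from the thyroid) tuned only to
#' reproduce the qualitative uptake-level trends of that literature, not its
#' numeric tables.
#'
#' @return named list of rates (per day) and dimensionless split fractions.
#' @export
iodide_default_constants <- function() {
  list(
    lambda_blood = 4.0,        # total clearance of blood iodide, /d
    f_urine = 0.60,            # blood outflow splits (of the non-thyroid share)
    f_salivary = 0.10,
    f_gastric = 0.15,
    f_placenta = 0.15,
    k_salivary = 5.0,          # salivary gland -> (swallowed) stomach, /d
    k_stomach = 4.0,           # gastric emptying, /d
    k_si = 3.5,                # small-intestine clearance, /d
    f_si_absorbed = 0.99,      # SI -> blood; remainder to feces
    k_kidney = 160.0,          # renal transit, /d
    k_thyroid_release = log(2) / 50,   # organic iodine release from thyroid
    k_metabolism = log(2) / 12,        # organic iodine turnover in the body
    f_met_liver = 0.5,         # organic turnover splits
    f_met_blood = 0.4,
    f_met_feces = 0.1,
    k_liver_release = 0.05,    # hepatic deiodination back to blood iodide
    k_fetal_thyroid = 1.35,    # fetal pool -> fetal thyroid
    k_fetal_back = 9.0,        # fetal pool -> maternal blood
    k_fetal_thy_release = log(2) / 50
  )
}

#' Iodide biokinetic model for pregnancy
#'
#' Builds the compartmental structure for radioiodide administered to a
#' pregnant patient: maternal blood iodide clears at a fixed total rate, a
#' fraction \code{F} (the maximum thyroid uptake) is trapped by the thyroid
#' and the remainder splits between renal excretion, salivary and gastric
#' secretion (both recycled through the gut) and transplacental transfer to a
#' fetal pool that feeds the fetal thyroid. Organically bound iodine released
#' by the thyroid passes through a body pool and the liver before recycling.
#' The blood-to-thyroid rate is \code{F * lambda_blood}, so absent physical
#' decay the asymptotic first-pass thyroid uptake equals \code{F}.
#'
#' @param F maximum thyroid uptake fraction, in (0, 1).
#' @param nuclide \code{"I-131"} or \code{"I-123"}.
#' @param constants rate-constant bundle, see
#'   \code{\link{iodide_default_constants}}.
#' @return a \code{compartment_model} with attributes \code{nuclide} and
#'   \code{uptake}.
#' @export
build_iodide_pregnancy_model <- function(F, nuclide = c("I-131", "I-123"),
                                         constants = iodide_default_constants()) {
  if (!(is.numeric(F) && length(F) == 1 && F > 0 && F < 1))
    stop("F must be in (0, 1)")
  nuclide <- match.arg(nuclide)
  need <- names(iodide_default_constants())
  if (!all(need %in% names(constants)))
    stop("missing constants: ",
         paste(setdiff(need, names(constants)), collapse = ", "))
  cs <- constants
  lb <- cs$lambda_blood
  comps <- c("blood", "thyroid", "salivary", "stomach", "si", "organic",
             "liver", "kidneys", "urine", "feces", "fetal_rest",
             "fetal_thyroid")
  tr <- rbind(
    data.frame(from = "blood", to = "thyroid",    rate = F * lb),
    data.frame(from = "blood", to = "salivary",   rate = cs$f_salivary * (1 - F) * lb),
    data.frame(from = "blood", to = "stomach",    rate = cs$f_gastric * (1 - F) * lb),
    data.frame(from = "blood", to = "kidneys",    rate = cs$f_urine * (1 - F) * lb),
    data.frame(from = "blood", to = "fetal_rest", rate = cs$f_placenta * (1 - F) * lb),
    data.frame(from = "salivary", to = "stomach", rate = cs$k_salivary),
    data.frame(from = "stomach", to = "si",       rate = cs$k_stomach),
    data.frame(from = "si", to = "blood",         rate = cs$f_si_absorbed * cs$k_si),
    data.frame(from = "si", to = "feces",         rate = (1 - cs$f_si_absorbed) * cs$k_si),
    data.frame(from = "thyroid", to = "organic",  rate = cs$k_thyroid_release),
    data.frame(from = "organic", to = "liver",    rate = cs$f_met_liver * cs$k_metabolism),
    data.frame(from = "organic", to = "blood",    rate = cs$f_met_blood * cs$k_metabolism),
    data.frame(from = "organic", to = "feces",    rate = cs$f_met_feces * cs$k_metabolism),
    data.frame(from = "liver", to = "blood",      rate = cs$k_liver_release),
    data.frame(from = "kidneys", to = "urine",    rate = cs$k_kidney),
    data.frame(from = "fetal_rest", to = "fetal_thyroid", rate = cs$k_fetal_thyroid),
    data.frame(from = "fetal_rest", to = "blood", rate = cs$k_fetal_back),
    data.frame(from = "fetal_thyroid", to = "fetal_rest",
               rate = cs$k_fetal_thy_release)
  )
  region_map <- c(blood = "remaining tissues", organic = "remaining tissues",
                  thyroid = "thyroid", salivary = "salivary glands",
                  stomach = "stomach", si = "small intestine",
                  liver = "liver", kidneys = "kidneys", urine = "urine",
                  feces = "feces", fetal_rest = "fetus remainder",
                  fetal_thyroid = "fetus thyroid")
  m <- compartment_model(comps, tr, nuclide_lambda_per_day(nuclide),
                         c(blood = 1), region_map,
                         excreta = c("urine", "feces"))
  attr(m, "nuclide") <- nuclide
  attr(m, "uptake") <- F
  m
}

#' Physical decay constant per day for the supported nuclides
#' @param nuclide \code{"I-131"}, \code{"I-123"} or \code{"Tc-99m"}.
#' @export
nuclide_lambda_per_day <- function(nuclide) {
  hl_h <- nuclide_half_life_hours(nuclide)
  log(2) / (hl_h / 24)
}

#' Solve the time-activity curves of a model
#'
#' Numerically integrates \eqn{dA/dt = (K - \lambda_p I) A} with
#' \code{deSolve::lsoda}.
#'
#' @param model a \code{compartment_model}.
#' @param times output times in hours (must include 0 or start later).
#' @return matrix, rows = times, columns = compartments.
#' @export
solve_compartments <- function(model, times) {
  stopifnot(!is.unsorted(times))
  M <- (model$K - diag(model$lambda_phys, length(model$compartments))) / 24
  f <- function(t, y, p) list(M %*% y)
  t0 <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::lsoda(model$A0, t0, f, NULL, rtol = 1e-10, atol = 1e-12)
  res <- out[match(times, out[, 1]), -1, drop = FALSE]
  colnames(res) <- model$compartments
  rownames(res) <- times
  res
}

#' Voiding-bladder cumulated activity
#'
#' Integrates the urinary bladder contents: the bladder accumulates the urine
#' inflow, decays physically, and empties at each void. This is the
#' conventional periodic-voiding treatment used for bladder contents (and,
#' via the transit compartment, the kidneys) when a biokinetic model routes
#' activity to urine.
#'
#' @param urine_inflow function of time (hours) returning the activity inflow
#'   rate into the bladder (per hour, per unit administered).
#' @param lambda_phys physical decay constant per day.
#' @param schedule list with \code{interval} and \code{first_void} in hours.
#' @param horizon integration horizon in hours (default: 12 physical
#'   half-lives, so the truncated tail is < 0.03\%).
#' @return cumulated activity of the bladder contents in hours.
#' @export
bladder_cumulated_activity <- function(urine_inflow, lambda_phys,
                                       schedule = voiding_schedule(),
                                       horizon = NULL) {
  stopifnot(schedule$interval > 0, schedule$first_void > 0)
  lam_h <- lambda_phys / 24
  if (is.null(horizon)) horizon <- 12 * log(2) / lam_h
  probe <- urine_inflow(seq(0, horizon, length.out = 100))
  if (any(probe < 0)) stop("negative urine inflow")
  voids <- unique(c(seq(schedule$first_void, horizon, by = schedule$interval),
                    horizon))
  f <- function(t, y, p)
    list(c(urine_inflow(t) - lam_h * y[1], y[1]))
  ev <- data.frame(var = "content", time = voids[voids < horizon],
                   value = 0, method = "rep")
  times <- sort(unique(c(seq(0, horizon, length.out = 2000), voids)))
  out <- deSolve::lsoda(c(content = 0, integral = 0), times, f, NULL,
                        rtol = 1e-9, atol = 1e-12,
                        events = if (nrow(ev)) list(data = ev) else NULL)
  unname(out[nrow(out), "integral"])
}

#' Default voiding schedule
#'
#' 3.5-hour voiding interval with the first void at 3.5 h -- the conventional
#' adult assumption; configurable.
#' @param interval,first_void hours.
#' @export
voiding_schedule <- function(interval = 3.5, first_void = interval)
  list(interval = interval, first_void = first_void)

#' Urine inflow function of a compartment model
#'
#' Returns a (vectorized) function of time in hours giving the activity flow
#' rate into urine, i.e. the renal transit outflow, for use with
#' \code{\link{bladder_cumulated_activity}}.
#'
#' @param model a \code{compartment_model} with a \code{kidneys} compartment
#'   whose outflow feeds \code{urine}.
#' @param horizon tabulation horizon in hours.
#' @export
urine_inflow_function <- function(model, horizon = NULL) {
  lam_h <- model$lambda_phys / 24
  if (is.null(horizon)) horizon <- 12 * log(2) / lam_h
  rate_h <- model$K["urine", "kidneys"] / 24
  tt <- sort(unique(c(0, exp(seq(log(1e-3), log(horizon), length.out = 600)))))
  A <- solve_compartments(model, tt)[, "kidneys"]
  f <- approx_fun_clamped(tt, rate_h * A)
  f
}

approx_fun_clamped <- function(x, y) {
  af <- stats::approxfun(x, y, rule = 2)
  function(t) pmax(af(t), 0)
}

#' Simulate noisy time-activity curves
#'
#' Multiplicative lognormal noise with the stated coefficient of variation
#' applied to the noiseless solution; the noise factors have mean 1.
#'
#' @param model a \code{compartment_model}.
#' @param times hours, sorted.
#' @param cv coefficient of variation (>= 0); 0 returns the noiseless curves.
#' @param seed RNG seed; the same seed reproduces the same curves.
#' @return matrix like \code{\link{solve_compartments}}.
#' @export
gen_time_activity <- function(model, times, cv = 0.05, seed = 1L) {
  stopifnot(cv >= 0, !is.unsorted(times))
  A <- solve_compartments(model, times)
  if (cv == 0) return(A)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  fac <- matrix(rlnorm(length(A), meanlog = -sdlog^2 / 2, sdlog = sdlog),
                nrow = nrow(A))
  A * fac
}

#' Fit free transfer rates to time-activity curves
#'
#' Least squares on log-activities over a caller-declared identifiable subset
#' of transfer rates, holding the remaining rates and the model structure
#' fixed.
#'
#' @param curves matrix of observed activities (rows = times given by its
#'   rownames, columns = compartments; missing compartments are ignored).
#' @param model a \code{compartment_model} giving the structure and the
#'   starting values.
#' @param free character vector of transfer identifiers \code{"from->to"}
#'   declaring which rates are free.
#' @param eps floor added inside the logs.
#' @return object of class \code{rate_fit}: \code{estimates} (named),
#'   \code{residual_norm}, \code{converged}, \code{model} (refitted).
#' @export
fit_rates <- function(curves, model, free, eps = 1e-12) {
  ids <- paste0(model$transfers$from, "->", model$transfers$to)
  idx <- match(free, ids)
  if (anyNA(idx)) stop("unknown transfer(s): ",
                       paste(free[is.na(idx)], collapse = ", "))
  times <- as.numeric(rownames(curves))
  obs <- curves[, intersect(colnames(curves), model$compartments),
                drop = FALSE]
  rebuild <- function(logrates) {
    tr <- model$transfers
    tr$rate[idx] <- exp(logrates)
    compartment_model(model$compartments, tr, model$lambda_phys,
                      model$A0[model$A0 > 0], model$region_map, model$excreta)
  }
  objective <- function(logrates) {
    m <- rebuild(logrates)
    pred <- solve_compartments(m, times)[, colnames(obs), drop = FALSE]
    sum((log(pred + eps) - log(obs + eps))^2)
  }
  p0 <- log(model$transfers$rate[idx])
  opt <- optim(p0, objective, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0)
    warning("fit_rates did not converge (code ", opt$convergence, ")")
  est <- setNames(exp(opt$par), free)
  structure(list(estimates = est, residual_norm = sqrt(opt$value),
                 converged = opt$convergence == 0, model = rebuild(opt$par)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("rate_fit:", if (x$converged) "converged" else "NOT converged",
      sprintf(" residual norm %.4g\n", x$residual_norm))
  for (nm in names(x$estimates))
    cat(sprintf("  %-24s %.6g /d\n", nm, x$estimates[nm]))
  invisible(x)
}
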
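# gas constant, kJ/(mol K)
R_GAS_KJ <- 8.314462618e-3

#' Simulate a 1:1 Langmuir SPR sensorgram
#'
#' Association phase \code{R(t) = Req (1 - exp(-(kon C + koff) t))} with
#' \code{Req = rmax kon C / (kon C + koff)}, followed by exponential
#' dissociation \code{R(t) = R0 exp(-koff (t - t0))}, with optional iid
#' Gaussian noise. Default contact/dissociation times follow common
#' single-cycle practice: 60 s contact, 300 s dissociation.
#'
#' @param kon association rate constant, 1/(M s)
#' @param koff dissociation rate constant, 1/s
#' @param rmax maximal response, RU
#' @param conc analyte concentration, M
#' @param tAssoc association (contact) time, s
#' @param tDissoc dissociation time, s
#' @param dt sampling interval, s
#' @param noiseSd Gaussian noise standard deviation, RU
#' @param seed optional RNG seed
#' @return data.frame(time_s, response_RU, conc_M, phase) with phase in
#'   \{"assoc", "dissoc"\}
#' @export
simulateSensorgram <- function(kon, koff, rmax, conc, tAssoc = 60,
                               tDissoc = 300, dt = 0.5, noiseSd = 0,
                               seed = NULL) {
  if (any(c(kon, koff, rmax, conc) < 0))
    .stopf("rates, rmax and concentration must be non-negative")
  tA <- seq(0, tAssoc, by = dt)
  tD <- seq(tAssoc + dt, tAssoc + tDissoc, by = dt)
  kObs <- kon * conc + koff
  req <- if (kObs > 0) rmax * kon * conc / kObs else 0
  rA <- req * (1 - exp(-kObs * tA))
  r0 <- req * (1 - exp(-kObs * tAssoc))
  rD <- r0 * exp(-koff * (tD - tAssoc))
  out <- data.frame(
    time_s = c(tA, tD),
    response_RU = c(rA, rD),
    conc_M = conc,
    phase = c(rep("assoc", length(tA)), rep("dissoc", length(tD))),
    stringsAsFactors = FALSE)
  if (noiseSd > 0) {
    out$response_RU <- out$response_RU +
      withSeed(seed, function() stats::rnorm(nrow(out), 0, noiseSd))
  }
  out
}

# model prediction for stacked sensorgram rows given linear-scale parameters
.langmuirPredict <- function(pars, d) {
  kon <- pars[1]; koff <- pars[2]; rmax <- pars[3]
  kObs <- kon * d$conc_M + koff
  req <- ifelse(kObs > 0, rmax * kon * d$conc_M / kObs, 0)
  r <- req * (1 - exp(-kObs * d$time_s))
  dis <- d$phase == "dissoc"
  if (any(dis)) {
    t0 <- d$t0[dis]
    r0 <- req[dis] * (1 - exp(-kObs[dis] * t0))
    r[dis] <- r0 * exp(-koff * (d$time_s[dis] - t0))
  }
  r
}

#' Global 1:1 Langmuir fit of a sensorgram panel
#'
#' Fits a single (kon, koff, Rmax) triple across all concentrations by
#' nonlinear least squares in log-parameter space (enforcing positivity and
#' improving conditioning), with multi-start over 8 log-spaced
#' initializations. KD = koff/kon is an identity of the result, never
#' refitted. Parameter standard deviations come from the fit covariance via
#' the delta method.
#'
#' @param panel stacked data.frame(time_s, response_RU, conc_M, phase) or a
#'   list of such per-concentration data.frames
#' @return a \linkS4class{KineticFit}
#' @export
fitKineticsGlobal <- function(panel) {
  if (is.data.frame(panel)) panel <- list(panel)
  d <- do.call(rbind, panel)
  need <- c("time_s", "response_RU", "conc_M", "phase")
  if (!all(need %in% names(d)))
    .stopf("sensorgram panel needs columns: %s", paste(need, collapse = ", "))
  if (!all(d$phase %in% c("assoc", "dissoc")))
    .stopf("phase must be 'assoc' or 'dissoc'")
  if (!any(d$phase == "assoc") || !any(d$phase == "dissoc"))
    .stopf("both association and dissociation phases are required")
  warnings <- character()
  if (length(unique(d$conc_M[d$conc_M > 0])) < 2)
    warnings <- c(warnings,
      "single analyte concentration: kon and rmax are weakly identifiable")
  # association end per concentration defines the dissociation clock origin
  t0ByConc <- tapply(d$time_s[d$phase == "assoc"], d$conc_M[d$phase == "assoc"],
                     max)
  d$t0 <- as.numeric(t0ByConc[as.character(d$conc_M)])
  if (anyNA(d$t0)) .stopf("every concentration needs an association phase")

  resid <- function(lp) d$response_RU - .langmuirPredict(exp(lp), d)
  rmax0 <- max(d$response_RU, 1e-3)
  starts <- expand.grid(kon = c(1e4, 1e6), koff = c(1e-3, 1e-1),
                        rmax = c(rmax0, 2 * rmax0))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(as.numeric(starts[i, ])), fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-10, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 * best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    .stopf("global kinetic fit failed to converge from all starts")
  fit <- best$fit
  lp <- fit$par
  n <- nrow(d)
  dof <- max(n - 3, 1)
  sigma2 <- best$rss / dof
  covL <- tryCatch(sigma2 * solve(fit$hessian / 2), error = function(e) {
    warnings <<- c(warnings, "singular fit covariance; sds set to NA")
    matrix(NA_real_, 3, 3)
  })
  kon <- exp(lp[1]); koff <- exp(lp[2]); rmax <- exp(lp[3])
  kd <- koff / kon
  # delta method: sd(x) = x * sd(log x); log kd = log koff - log kon
  varLkd <- covL[2, 2] + covL[1, 1] - 2 * covL[1, 2]
  sds <- c(kon = kon * sqrt(covL[1, 1]), koff = koff * sqrt(covL[2, 2]),
           rmax = rmax * sqrt(covL[3, 3]), kd = kd * sqrt(max(varLkd, 0)))
  new("KineticFit", kon = kon, koff = koff, rmax = rmax, kd = kd,
      sd = sds, rss = best$rss, nObs = as.integer(n), warnings = warnings)
}

#' Read a sensorgram CSV
#'
#' Columns: time_s, response_RU, conc_M, phase ("assoc"/"dissoc").
#'
#' @param file path
#' @return data.frame
#' @export
readSensorgramCSV <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("time_s", "response_RU", "conc_M", "phase")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .stopf("sensorgram CSV lacks columns: %s", paste(miss, collapse = ", "))
  d
}

#' Van't Hoff fit of KD versus temperature
#'
#' Linear regression of ln KD on 1/T under
#' \code{ln KD = dH/(R T) - dS/R}: the slope is dH/R and the intercept is
#' -dS/R. Unweighted by default; optional per-point weights. The (dH, dS)
#' covariance is stored for downstream error propagation.
#'
#' @param temperature_K temperatures, K (>= 3 values)
#' @param kd_M equilibrium dissociation constants, M (> 0)
#' @param weights optional regression weights
#' @param refT reference temperature for the reported dG, K
#' @return a \linkS4class{VantHoffFit}
#' @export
vantHoffFit <- function(temperature_K, kd_M, weights = NULL, refT = 298) {
  if (length(temperature_K) < 3)
    .stopf("van't Hoff fit needs at least 3 temperatures, got %d",
           length(temperature_K))
  if (length(kd_M) != length(temperature_K))
    .stopf("temperature and KD vectors differ in length")
  if (any(kd_M <= 0)) .stopf("all KD values must be positive")
  x <- 1 / temperature_K
  y <- log(kd_M)
  fit <- if (is.null(weights)) stats::lm(y ~ x)
         else stats::lm(y ~ x, weights = weights)
  b <- stats::coef(fit)
  # noiseless inputs fit exactly; the zero-residual covariance is fine here
  V <- suppressWarnings(stats::vcov(fit))
  dH <- R_GAS_KJ * b[["x"]]
  dS <- -R_GAS_KJ * b[["(Intercept)"]]
  covHS <- matrix(c(R_GAS_KJ^2 * V["x", "x"],
                    -R_GAS_KJ^2 * V["(Intercept)", "x"],
                    -R_GAS_KJ^2 * V["(Intercept)", "x"],
                    R_GAS_KJ^2 * V["(Intercept)", "(Intercept)"]),
                  2, 2, dimnames = list(c("dH", "dS"), c("dH", "dS")))
  # exact (noiseless) inputs make lm() covariance collapse to ~0; keep >= 0
  covHS[!is.finite(covHS)] <- 0
  dG <- dH - refT * dS
  sdG <- sqrt(max(covHS[1, 1] + refT^2 * covHS[2, 2] -
                  2 * refT * covHS[1, 2], 0))
  new("VantHoffFit", dH = dH, dS = dS, refT = refT, dG = dG,
      sd = c(dH = sqrt(max(covHS[1, 1], 0)), dS = sqrt(max(covHS[2, 2], 0)),
             dG = sdG),
      cov = covHS, nT = length(temperature_K))
}

#' Error-propagated binding free energy at a temperature
#'
#' \code{dG = dH - T dS} with
#' \code{var(dG) = var(dH) + T^2 var(dS) - 2 T cov(dH, dS)} when the
#' covariance term is used, or without the cross term otherwise.
#'
#' @param fit a \linkS4class{VantHoffFit}
#' @param T temperature, K
#' @param useCovariance include the (dH, dS) covariance cross term
#' @return named numeric c(dG, sd), kJ/mol
#' @export
deltaGPropagated <- function(fit, T = fit@refT, useCovariance = TRUE) {
  dG <- fit@dH - T * fit@dS
  v <- fit@cov[1, 1] + T^2 * fit@cov[2, 2]
  if (useCovariance) v <- v - 2 * T * fit@cov[1, 2]
  c(dG = dG, sd = sqrt(max(v, 0)))
}

#' Apparent melting temperature from a DSC thermogram
#'
#' Returns the temperature of the global heat-capacity maximum after
#' optional moving-average smoothing, refined by a quadratic fit through
#' the three grid points around the maximum. Inputs with more than one
#' prominent peak (local maxima rising above 25\% of the scan range over the
#' baseline) are flagged rather than rejected, since broad or shouldered
#' transitions are biologically meaningful.
#'
#' @param temperature_C scan temperatures, degrees C (>= 5 points)
#' @param cp heat capacity, arbitrary units
#' @param smoothWindow odd moving-average window length (NULL = none)
#' @return a \linkS4class{TmResult}
#' @export
tmApp <- function(temperature_C, cp, smoothWindow = NULL) {
  n <- length(temperature_C)
  if (n < 5) .stopf("thermogram needs at least 5 points, got %d", n)
  if (length(cp) != n) .stopf("temperature and cp vectors differ in length")
  y <- cp
  win <- 0L
  if (!is.null(smoothWindow) && smoothWindow > 1) {
    win <- as.integer(smoothWindow)
    if (win %% 2 == 0) win <- win + 1L
    y <- stats::filter(cp, rep(1 / win, win), sides = 2)
    y <- as.numeric(y)
    pad <- (win - 1) / 2
    y[seq_len(pad)] <- y[pad + 1]
    y[(n - pad + 1):n] <- y[n - pad]
  }
  rng <- diff(range(y))
  if (rng <= 0) .stopf("flat thermogram: no peak")
  i <- which.max(y)
  if (i == 1 || i == n)
    .stopf("heat-capacity maximum lies at the scan boundary: no interior peak")
  # quadratic refinement through the three points around the grid maximum
  t3 <- temperature_C[(i - 1):(i + 1)]
  y3 <- y[(i - 1):(i + 1)]
  s1 <- (y3[2] - y3[1]) / (t3[2] - t3[1])
  s2 <- (y3[3] - y3[2]) / (t3[3] - t3[2])
  a <- (s2 - s1) / (t3[3] - t3[1])
  tm <- if (abs(a) > 1e-12) {
    b <- s1 - a * (t3[1] + t3[2])
    -b / (2 * a)
  } else t3[2]
  # prominent local maxima for multi-peak flagging
  loc <- which(diff(sign(diff(y))) < 0) + 1L
  prom <- loc[y[loc] >= min(y) + 0.25 * rng]
  nPeaks <- max(length(prom), 1L)
  new("TmResult", tmApp = tm, multiPeak = nPeaks > 1,
      nPeaks = as.integer(nPeaks), smoothWindow = win)
}
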
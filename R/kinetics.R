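# Deamination kinetics: rate computation from product fractions,
# linearized Michaelis-Menten fitting, and amplicon mixture
# quantification.

#' Deamination rate from product fractions
#'
#' The observable is the deaminated-product fraction I_D / (I_U + I_D),
#' which equals rate * [E] * t, so rate = fraction / ([E] * t). Units
#' follow the printed convention (the fraction is dimensionless; [E] in
#' uM, t in min).
#'
#' @param I_D,I_U deaminated / undeaminated product intensities (>= 0,
#'   not both 0). Vectorized.
#' @param E enzyme concentration (uM, > 0).
#' @param t reaction time (min, > 0).
#' @return deamination rate(s).
#' @examples
#' deaminationRate(1, 1, E = 1, t = 5)  # 0.1
#' @export
deaminationRate <- function(I_D, I_U, E, t) {
  if (any(I_D < 0 | I_U < 0)) stop("intensities must be >= 0")
  if (any(I_D + I_U == 0)) stop("I_D + I_U must be > 0")
  if (E <= 0 || t <= 0) stop("E and t must be > 0")
  (I_D / (I_U + I_D)) / (E * t)
}

#' Fit Michaelis-Menten parameters by linear regression
#'
#' Linearizes the Michaelis-Menten equation and fits by ordinary least
#' squares, as the kinetic constants are obtained by linear regression
#' analysis rather than nonlinear fitting. The default double-reciprocal
#' (Lineweaver-Burk) form regresses 1/rate on 1/[S]; K_M = slope /
#' intercept and k_cat = 1 / intercept. The Hanes-Woolf form ([S]/rate on
#' [S]) is available and agrees exactly on noise-free data.
#'
#' @param points data.frame with columns S_uM, E_uM, t_min and
#'   frac_deaminated (as from [simulateKinetics()]), or S_uM and rate.
#' @param method "lineweaver-burk" (default) or "hanes-woolf".
#' @return A [KineticFit-class]; `valid` is FALSE when the linearization
#'   intercept (Lineweaver-Burk) or slope (Hanes-Woolf) is <= 0.
#' @export
fitMichaelisMenten <- function(points,
                               method = c("lineweaver-burk", "hanes-woolf")) {
  method <- match.arg(method)
  points <- as.data.frame(points)
  S <- points$S_uM
  rate <- if (!is.null(points$rate)) points$rate
          else deaminationRate(points$frac_deaminated,
                               1 - points$frac_deaminated,
                               E = points$E_uM[1L], t = points$t_min[1L])
  if (length(unique(S)) < 2L)
    stop("need at least 2 distinct substrate concentrations")
  if (any(rate <= 0))
    stop("non-positive rate: the linearization needs all rates > 0")

  if (method == "lineweaver-burk") { x <- 1 / S; y <- 1 / rate }
  else { x <- S; y <- S / rate }
  fit <- stats::lm(y ~ x)
  b <- unname(coef(fit)[2L]); a <- unname(coef(fit)[1L])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst

  if (method == "lineweaver-burk") {
    valid <- is.finite(a) && a > 0
    k_cat <- 1 / a
    K_M <- b / a
  } else {
    valid <- is.finite(b) && b > 0
    k_cat <- 1 / b
    K_M <- a / b
  }
  eff <- if (K_M == 0) Inf else k_cat / K_M
  new("KineticFit", k_cat = k_cat, K_M = K_M, efficiency = eff,
      slope = b, intercept = a, r_squared = r2, valid = valid,
      method = method)
}

#' Per-site measured C/(C+T) on an amplicon read set
#'
#' For each original-C position of the amplicon (plus strand), the
#' fraction of full-length reads showing C. Sites with zero C+T coverage
#' are omitted with a warning.
#'
#' @param reads a [ReadSet-class] from [simulateColonies()] or
#'   [simulateMixture()] (full-length plus-strand molecules).
#' @param substrate the amplicon reference sequence.
#' @return data.frame(pos0, context5p, N_C, N_T, fraction).
#' @export
ampliconSiteFractions <- function(reads, substrate) {
  sstr <- .asSeqString(substrate)
  s <- .explode(sstr)
  cpos <- which(s == "C")
  seqs <- readSequences(reads)
  n <- length(seqs)
  if (n == 0L || !length(cpos)) {
    warning("no covered cytosine sites")
    return(data.frame(pos0 = integer(0), context5p = character(0),
                      N_C = integer(0), N_T = integer(0),
                      fraction = numeric(0)))
  }
  if (any(Biostrings::width(seqs) != length(s)))
    stop("reads must be full-length amplicon molecules")
  bytes <- charToRaw(paste(as.character(seqs), collapse = ""))
  L <- length(s)
  lin <- rep(cpos, times = n) + (rep(seq_len(n), each = length(cpos)) - 1L) * L
  bv <- bytes[lin]
  nC <- tapply(bv == .RAW_C, rep(seq_along(cpos), times = n), sum)
  nT <- tapply(bv == .RAW_T, rep(seq_along(cpos), times = n), sum)
  out <- data.frame(pos0 = cpos - 1L,
                    context5p = c(NA_character_, s[-L])[cpos],
                    N_C = as.integer(nC), N_T = as.integer(nT),
                    stringsAsFactors = FALSE)
  drop <- out$N_C + out$N_T == 0L
  if (any(drop)) {
    warning(sprintf("%d site(s) with zero C+T coverage omitted", sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  out$fraction <- out$N_C / (out$N_C + out$N_T)
  rownames(out) <- NULL
  out
}

#' Regress measured C/(C+T) on theoretical 5hmC fraction
#'
#' Ordinary least squares of the measured per-mixture ratios on the
#' theoretical 5hmC percentages; a slope near 1 with high R-squared is the
#' linearity evidence that the assay quantifies 5hmC stoichiometry.
#'
#' @param measured measured C/(C+T) values.
#' @param theoretical theoretical 5hmC fractions in [0, 1], same length
#'   (>= 3), non-constant.
#' @return A [MixtureRegression-class].
#' @export
mixtureRegression <- function(measured, theoretical) {
  if (length(measured) != length(theoretical))
    stop("measured and theoretical must have equal length")
  if (length(measured) < 3L) stop("need at least 3 mixture points")
  if (any(theoretical < 0 | theoretical > 1))
    stop("theoretical fractions must be in [0, 1]")
  if (var(theoretical) == 0)
    stop("zero variance in theoretical fractions")
  fit <- stats::lm(measured ~ theoretical)
  sst <- sum((measured - mean(measured))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  new("MixtureRegression", slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]), r_squared = r2,
      n = length(measured))
}
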
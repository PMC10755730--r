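#' Construct a deamination model
#'
#' Returns the per-state, per-5'-context deamination probabilities for one
#' of the two characterized deaminases, or a custom model. The shipped
#' defaults are the colony-sequencing conversion rates: the engineered
#' eA3A-v10 deaminates C at 99.92% and 5mC at 99.52% while converting only
#' 0.16% of 5hmC; wild-type A3A converts C at 100.00%, 5mC at 99.68% and
#' 5hmC at 80.71%. Neither default enzyme shows sequence-context bias, so
#' the cells are uniform across the four 5'-neighbor contexts; pass `prob`
#' to express a context-biased enzyme.
#'
#' @param enzyme "eA3A-v10", "wtA3A", or any name when `prob` is supplied.
#' @param prob optional 3 x 4 matrix (rows C/5mC/5hmC, columns A/C/G/T).
#' @return A [DeaminationModel-class] object.
#' @examples
#' deaminationModel("eA3A-v10")
#' @export
deaminationModel <- function(enzyme = c("eA3A-v10", "wtA3A"), prob = NULL) {
  if (is.null(prob)) {
    enzyme <- match.arg(enzyme)
    cells <- switch(enzyme,
                    "eA3A-v10" = c(C = 0.9992, `5mC` = 0.9952, `5hmC` = 0.0016),
                    "wtA3A"    = c(C = 1.0000, `5mC` = 0.9968, `5hmC` = 0.8071))
    prob <- matrix(rep(cells, 4L), nrow = 3L,
                   dimnames = list(.MOD_STATES, .CONTEXTS))
  } else {
    enzyme <- as.character(enzyme)[1L]
    prob <- as.matrix(prob)
    if (is.null(rownames(prob))) rownames(prob) <- .MOD_STATES
    if (is.null(colnames(prob))) colnames(prob) <- .CONTEXTS
  }
  new("DeaminationModel", enzyme = enzyme, prob = prob)
}

#' Default steady-state kinetic parameters
#'
#' Per (enzyme, substrate state): the catalytic constants and the assay
#' design (enzyme concentration, reaction time, substrate range) used to
#' generate synthetic deamination-rate data. Only the catalytic efficiency
#' k_cat/K_M is an externally reported constant; the (k_cat, K_M) split is
#' this package's choice, with K_M placed inside each assay's substrate
#' range so the linearized fit is well conditioned (see the methods
#' vignette). eA3A-v10 activity on 5hmC is too low for kinetic constants
#' and is therefore absent.
#'
#' @return data.frame with columns enzyme, state, k_cat (min^-1), K_M (uM),
#'   efficiency (uM^-1 min^-1), E_uM, t_min, S_min, S_max.
#' @examples
#' kineticDefaults()
#' @export
kineticDefaults <- function() {
  data.frame(
    enzyme     = c("eA3A-v10", "eA3A-v10", "wtA3A", "wtA3A", "wtA3A"),
    state      = c("C", "5mC", "C", "5mC", "5hmC"),
    k_cat      = c(3.135, 1.950, 9.082, 4.490, 0.080),
    K_M        = c(0.50, 0.50, 0.10, 0.20, 0.25),
    efficiency = c(6.27, 3.90, 90.82, 22.45, 0.32),
    E_uM       = c(0.04, 0.04, 0.01, 0.01, 1.00),
    t_min      = c(5, 5, 5, 5, 5),
    S_min      = c(0.1, 0.1, 0.1, 0.1, 0.025),
    S_max      = c(2.5, 2.5, 2.5, 2.5, 1.25),
    stringsAsFactors = FALSE
  )
}

#' Default substrate concentration series for a kinetic assay
#'
#' Six concentrations spanning the assay range: 0.1-2.5 uM for C and 5mC
#' substrates, 0.025-1.25 uM for 5hmC substrates.
#'
#' @param state substrate state ("C", "5mC" or "5hmC").
#' @return numeric vector of substrate concentrations (uM).
#' @export
substrateSeries <- function(state = c("C", "5mC", "5hmC")) {
  state <- match.arg(state)
  if (state == "5hmC") c(0.025, 0.05, 0.1, 0.25, 0.5, 1.25)
  else c(0.1, 0.25, 0.5, 1.0, 1.5, 2.5)
}
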
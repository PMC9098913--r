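# Hill-equation fits for bulk binding assays and membrane-packing geometry
# calculators.

# Model evaluators (shared with the synthetic-curve generator).
hillQcmd <- function(x, S, E, n, k) {
  S + (E - S) * ifelse(x > 0, x^n / (k^n + x^n), 0)
}

hillMst <- function(C, U, B, EC50, n) {
  ifelse(C > 0, U + (B - U) / (1 + (EC50 / C)^n), U)
}

checkSpan <- function(conc, k, label) {
  pos <- conc[conc > 0]
  if (!length(pos) || k < min(pos) || k > max(conc)) {
    warning(sprintf(
      "fitted %s = %.4g uM is not bracketed by the measured concentrations",
      label, k))
  }
}

#' Hill fit to a QCM-D frequency-shift isotherm
#'
#' Fits y = S + (E - S) x^n / (k^n + x^n) to a (concentration, response)
#' series, with S/E the start/end responses, n the Hill coefficient and k
#' the dissociation constant. Responses keep their native sign; QCM-D
#' frequency shifts are negative on binding, so E < S is the usual case.
#' n is bounded to \[0.2, 10\] and k to positive values; fits ending at a
#' bound are flagged.
#'
#' @param series A [BindingSeries-class] with at least 4 points. A warning
#'   is emitted when the fitted k is not bracketed by the measured
#'   concentrations.
#' @param fixN optionally fix the Hill coefficient (e.g. `fixN = 1` for a
#'   Langmuir isotherm) instead of fitting it.
#' @return A [FitResult-class] with `S`, `E`, `n`, `k` (uM).
#' @export
fitHillQcmd <- function(series, fixN = NULL) {
  stopifnot(is(series, "BindingSeries"))
  x <- series@concentrations
  y <- series@responses
  if (length(x) < 4L) stop("need at least 4 points for a Hill fit")
  pos <- x[x > 0]
  k0 <- if (length(pos)) exp(mean(log(range(pos)))) else 1
  fit <- if (is.null(fixN)) {
    par0 <- c(S = y[1], E = y[length(y)], n = 1, k = k0)
    fn <- function(p) hillQcmd(x, p[["S"]], p[["E"]], p[["n"]], p[["k"]]) - y
    lmFit(par0, fn,
          lower = c(S = -Inf, E = -Inf, n = 0.2, k = 1e-9),
          upper = c(S = Inf, E = Inf, n = 10, k = Inf),
          modelName = "hill_qcmd", obs = y)
  } else {
    par0 <- c(S = y[1], E = y[length(y)], k = k0)
    fn <- function(p) hillQcmd(x, p[["S"]], p[["E"]], fixN, p[["k"]]) - y
    f <- lmFit(par0, fn, lower = c(S = -Inf, E = -Inf, k = 1e-9),
               modelName = "hill_qcmd", obs = y)
    f@params <- c(f@params[c("S", "E")], n = fixN, f@params["k"])
    f@stderr <- c(f@stderr[c("S", "E")], n = NA_real_, f@stderr["k"])
    f
  }
  checkSpan(x, fitParams(fit)[["k"]], "k")
  if (isTRUE(fit@diagnostics$atBound)) fit@converged <- FALSE
  fit
}

#' Hill fit to an MST dose-response series
#'
#' Fits y = U + (B - U) / (1 + (EC50 / C)^n), with U/B the unbound/bound
#' signals; same bounds and flagging as [fitHillQcmd()].
#'
#' @param series A [BindingSeries-class] with at least 4 points.
#' @return A [FitResult-class] with `U`, `B`, `EC50` (uM), `n`.
#' @export
fitHillMst <- function(series) {
  stopifnot(is(series, "BindingSeries"))
  x <- series@concentrations
  y <- series@responses
  if (length(x) < 4L) stop("need at least 4 points for a Hill fit")
  pos <- x[x > 0]
  e0 <- if (length(pos)) exp(mean(log(range(pos)))) else 1
  par0 <- c(U = y[1], B = y[length(y)], EC50 = e0, n = 1)
  fn <- function(p) hillMst(x, p[["U"]], p[["B"]], p[["EC50"]], p[["n"]]) - y
  fit <- lmFit(par0, fn,
               lower = c(U = -Inf, B = -Inf, EC50 = 1e-9, n = 0.2),
               upper = c(U = Inf, B = Inf, EC50 = Inf, n = 10),
               modelName = "hill_mst", obs = y)
  checkSpan(x, fitParams(fit)[["EC50"]], "EC50")
  if (isTRUE(fit@diagnostics$atBound)) fit@converged <- FALSE
  fit
}

#' Hexagonal-lattice area per molecule from a surface density
#'
#' For a protein density x in pmol/cm^2, the area available per molecule on
#' a hexagonal lattice is y = 2/sqrt(3) * 1 / (6.022 x 0.001) nm^2
#' (6.022e-4 converts pmol/cm^2 to molecules/nm^2; 2/sqrt(3) is the
#' hexagonal packing factor).
#'
#' @param proteinDensity pmol/cm^2, positive.
#' @return Area per molecule, nm^2.
#' @examples
#' latticeSpacing(1)  # 191.75 nm^2
#' @export
latticeSpacing <- function(proteinDensity) {
  if (!is.numeric(proteinDensity) || any(proteinDensity <= 0)) {
    stop("proteinDensity must be positive (pmol/cm^2)")
  }
  2 / sqrt(3) * 1 / (6.022 * proteinDensity * 0.001)
}

#' Theoretical maximum membrane packing of an anchored protein
#'
#' With a molecular footprint A_p and a lipid headgroup area A_l, a single
#' molecule covers A_p / A_l lipids, so the anchor-lipid (Tris-NTA) mole
#' fraction that saturates the membrane is 100 / (A_p / A_l) percent. For
#' a 30 nm^2 footprint and 0.5 nm^2 lipids this gives 60 lipids per
#' molecule and a saturating density of 100/60 = 1.666...%, conventionally
#' printed as 1.66% (two decimals, truncated); the exact value is returned
#' alongside the truncated one.
#'
#' @param footprintNm2 protein footprint, nm^2.
#' @param lipidAreaNm2 area per lipid, nm^2 (default 0.5).
#' @return list with `lipidsPerMolecule`, `saturatingTrisNtaPercent`
#'   (exact) and `saturatingTrisNtaPercentReported` (two decimals,
#'   truncated).
#' @examples
#' maxPacking(30)
#' @export
maxPacking <- function(footprintNm2, lipidAreaNm2 = 0.5) {
  if (footprintNm2 <= 0 || lipidAreaNm2 <= 0) {
    stop("footprint and lipid area must be positive")
  }
  lipids <- footprintNm2 / lipidAreaNm2
  sat <- 100 / lipids
  list(lipidsPerMolecule = lipids,
       saturatingTrisNtaPercent = sat,
       saturatingTrisNtaPercentReported = floor(sat * 100) / 100)
}
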
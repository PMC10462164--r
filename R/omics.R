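## Threshold-based proteomics set analytics and small closed-form assay
## computations (relative qPCR expression, bead-capture fold change,
## densitometry ratio).

#' Two-set partition counts
#'
#' Exact partition of two identifier sets into A-only, B-only and common
#' members, as used for protein presence/absence comparisons.
#'
#' @param setA,setB character (or atomic) vectors of identifiers;
#'   duplicates are ignored
#' @return named integer vector \code{c(aOnly, bOnly, common)}
#' @examples
#' vennPartition(c("P1", "P2", "P3"), c("P2", "P3", "P4"))
#' @export
vennPartition <- function(setA, setB) {
  a <- unique(setA); b <- unique(setB)
  common <- length(intersect(a, b))
  c(aOnly = length(a) - common, bOnly = length(b) - common,
    common = common)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, order-preserving
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential protein filter: fold change and FDR cutoffs
#'
#' Per protein: the group ratio on the linear scale computed from log2
#' group means (geometric-mean ratio), a Welch two-sample t-test on log2
#' abundances, Benjamini-Hochberg adjustment, and a significance flag for
#' |log2 fold change| passing \code{fcMin} together with adjusted
#' p <= \code{fdrMax}.  Proteins with zero variance in both groups get a
#' degenerate (NA) p-value and do not enter the adjustment.
#'
#' @param abundance linear-scale matrix, proteins x samples (all > 0)
#' @param group two-level factor over the columns
#' @param fcMin minimum linear fold change in either direction
#' @param fdrMax maximum FDR-adjusted p-value
#' @return list: \code{table} (data.frame: protein, foldChange, log2Fc,
#'   p, fdr, significant), \code{upInGroup2}, \code{upInGroup1} counts
#'   (significant proteins with fold change >= fcMin resp. <= 1/fcMin)
#' @export
differentialFilter <- function(abundance, group, fcMin = 2,
                               fdrMax = 0.05) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L, ncol(abundance) == length(group),
            all(abundance > 0))
  lv <- levels(group)
  if (any(table(group) < 2)) stop("need >= 2 replicates per group")
  la <- log2(abundance)
  i1 <- group == lv[1]; i2 <- group == lv[2]
  p <- numeric(nrow(la))
  for (i in seq_len(nrow(la))) {
    x <- la[i, i1]; y <- la[i, i2]
    p[i] <- if (sd(x) == 0 && sd(y) == 0) NA_real_
            else t.test(y, x, var.equal = FALSE)$p.value
  }
  log2fc <- rowMeans(la[, i2, drop = FALSE]) -
    rowMeans(la[, i1, drop = FALSE])
  fdr <- bhAdjust(p)
  sig <- !is.na(fdr) & fdr <= fdrMax & abs(log2fc) >= log2(fcMin)
  tab <- data.frame(protein = rownames(abundance) %||%
                      as.character(seq_len(nrow(abundance))),
                    foldChange = 2^log2fc, log2Fc = log2fc, p = p,
                    fdr = fdr, significant = sig)
  list(table = tab,
       upInGroup2 = sum(sig & log2fc > 0),
       upInGroup1 = sum(sig & log2fc < 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - mean Ct over the housekeeping genes
#' (arithmetic mean of Ct, i.e. geometric mean on the expression scale);
#' ddCt is the group-mean dCt minus the calibrator-group-mean dCt, and the
#' relative expression is 2^-ddCt.
#'
#' @param ct data.frame with columns \code{sample, gene, ct, group}
#' @param targetGene gene of interest
#' @param sampleGroup group whose expression is reported
#' @param calibratorGroup reference group
#' @param housekeeping housekeeping gene set (all must be present in every
#'   sample)
#' @return relative expression 2^-ddCt (1 = no change vs calibrator)
#' @export
ddct <- function(ct, targetGene, sampleGroup, calibratorGroup,
                 housekeeping = c("ACTB", "GAPDH", "B2M")) {
  stopifnot(all(c("sample", "gene", "ct", "group") %in% names(ct)),
            all(ct$ct > 0))
  dct <- vapply(unique(ct$sample), function(s) {
    rows <- ct[ct$sample == s, , drop = FALSE]
    tgt <- rows$ct[rows$gene == targetGene]
    hk <- rows$ct[match(housekeeping, rows$gene)]
    if (length(tgt) != 1L || anyNA(hk))
      stop("missing target or housekeeping Ct in sample ", s)
    tgt - mean(hk)
  }, numeric(1))
  grp <- ct$group[match(unique(ct$sample), ct$sample)]
  if (!sampleGroup %in% grp || !calibratorGroup %in% grp)
    stop("sampleGroup and calibratorGroup must both be present")
  ddctVal <- mean(dct[grp == sampleGroup]) -
    mean(dct[grp == calibratorGroup])
  2^(-ddctVal)
}

#' Fold change of vesicle secretion from a bead-capture assay
#'
#' Arbitrary units per condition are fluorescence times percent positive
#' beads normalised to the number of viable cells; the fold change is the
#' treatment-to-control ratio of these units.
#'
#' @param treatment,control named lists (or vectors) with elements
#'   \code{fluorescence} (AU), \code{percentPositive} (percent) and
#'   \code{viableCells} (count > 0)
#' @return fold change (unitless)
#' @examples
#' beadFoldChange(list(fluorescence = 1000, percentPositive = 50,
#'                     viableCells = 1e4),
#'                list(fluorescence = 500, percentPositive = 25,
#'                     viableCells = 1e4))  # 4
#' @export
beadFoldChange <- function(treatment, control) {
  au <- function(x) {
    stopifnot(x$viableCells > 0)
    x$fluorescence * x$percentPositive / x$viableCells
  }
  auC <- au(control)
  if (auC <= 0) stop("control arbitrary units must be positive")
  au(treatment) / auC
}

#' Loading-control-normalised densitometry fold change
#'
#' Band intensity in the test sample over the reference sample, each first
#' normalised to its own loading-control band.
#'
#' @param band,loading band and loading-control intensities, test sample
#' @param bandRef,loadingRef the same for the reference sample
#' @return fold change (unitless)
#' @export
densitometryRatio <- function(band, loading, bandRef, loadingRef) {
  stopifnot(band > 0, loading > 0, bandRef > 0, loadingRef > 0)
  (band / loading) / (bandRef / loadingRef)
}
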
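#' Relative gene expression by the comparative-Ct (2^-ddCt) method
#'
#' For every sample and target gene: `dCt = Ct(target) - Ct(housekeeping)`;
#' `ddCt = dCt(sample) - dCt(reference sample)`; fold change `2^-ddCt`.
#' Technical-replicate Ct values (several rows for one sample/gene) are
#' averaged before dCt. Undetected wells (`NA` Ct) propagate as flagged
#' missing fold changes; they are never imputed.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` (cycles; `NA`
#'   for undetected).
#' @param housekeeping_gene housekeeping gene used for dCt (default
#'   `"GAPDH"`).
#' @param reference_sample sample whose expression defines fold change 1.
#' @return data.frame with one row per sample x target gene: `sample`,
#'   `gene`, `delta_ct`, `delta_delta_ct`, `fold_change`, `flagged`
#'   (`TRUE` when a Ct was undetected and the fold is `NA`).
#' @examples
#' ct <- data.frame(
#'   sample = rep(c("ref", "treated"), each = 2),
#'   gene = rep(c("CDKN1A", "GAPDH"), 2),
#'   ct = c(25, 20, 23, 20)
#' )
#' delta_delta_ct(ct, reference_sample = "ref")
#' @export
delta_delta_ct <- function(ct, housekeeping_gene = "GAPDH", reference_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0, na.rm = TRUE)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  if (!reference_sample %in% ct$sample) {
    stop(sprintf("reference sample '%s' not present", reference_sample), call. = FALSE)
  }
  if (!housekeeping_gene %in% ct$gene) {
    stop(sprintf("housekeeping gene '%s' not present", housekeeping_gene), call. = FALSE)
  }
  # average technical replicates; an undetected replicate poisons the mean
  mean_ct <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean,
    na.action = stats::na.pass
  )
  hk <- mean_ct[mean_ct$gene == housekeeping_gene, c("sample", "ct")]
  names(hk)[2] <- "hk_ct"
  tg <- mean_ct[mean_ct$gene != housekeeping_gene, ]
  if (!nrow(tg)) stop("no target genes in table", call. = FALSE)
  d <- merge(tg, hk, by = "sample", all.x = TRUE)
  if (anyNA(d$hk_ct) && any(!d$sample %in% hk$sample)) {
    stop("every sample needs a housekeeping Ct", call. = FALSE)
  }
  d$delta_ct <- d$ct - d$hk_ct
  ref <- d[d$sample == reference_sample, c("gene", "delta_ct")]
  names(ref)[2] <- "ref_delta_ct"
  d <- merge(d, ref, by = "gene", all.x = TRUE)
  d$delta_delta_ct <- d$delta_ct - d$ref_delta_ct
  d$fold_change <- 2^(-d$delta_delta_ct)
  d$flagged <- !is.finite(d$fold_change)
  d$fold_change[d$flagged] <- NA_real_
  out <- d[order(d$gene, d$sample), c(
    "sample", "gene", "delta_ct", "delta_delta_ct", "fold_change", "flagged"
  )]
  rownames(out) <- NULL
  out
}
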
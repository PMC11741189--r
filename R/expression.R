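#' Relative gene expression by the 2^-ddCt method
#'
#' Computes per-sample fold changes relative to a control group with a
#' reference gene: for each sample and target gene,
#' `dCt = Ct_gene - Ct_reference`; `ddCt = dCt - mean(dCt)` over the
#' control-group samples of that gene; `fold = 2^-ddCt`. Technical
#' replicates (several rows for one sample x gene) are averaged to a single
#' Ct before the calculation. By construction the geometric mean of the
#' control-group fold changes is exactly 1 for every gene.
#'
#' @param records data frame of Ct measurements with columns `sample_id`,
#'   `group`, `gene`, `ct`.
#' @param reference_gene name of the reference (housekeeping) gene, e.g.
#'   18S ribosomal RNA.
#' @param control_group group label used as the calibrator.
#' @return List with `samples` (per-sample `sample_id`, `group`, `gene`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`), `groups` (per
#'   group x gene `mean_fold`, `sem_fold`, `mean_log2_fold`, `sem_log2_fold`,
#'   `n`), and `errors` (samples lacking a reference Ct).
#' @export
delta_delta_ct <- function(records, reference_gene, control_group) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "group", "gene", "ct") %in% names(records)))
  if (!any(records$group == control_group))
    stop(sprintf("control group '%s' not present", control_group),
         call. = FALSE)
  if (!any(records$gene == reference_gene))
    stop(sprintf("reference gene '%s' not present", reference_gene),
         call. = FALSE)
  if (any(!is.finite(records$ct)))
    stop("all Ct values must be finite", call. = FALSE)

  # average technical replicates to one Ct per sample x gene
  ag <- stats::aggregate(ct ~ sample_id + group + gene, data = records,
                         FUN = mean)
  ref <- ag[ag$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ref_ct"
  targets <- ag[ag$gene != reference_gene, , drop = FALSE]
  m <- merge(targets, ref, by = "sample_id", all.x = TRUE)

  errors <- m[is.na(m$ref_ct), c("sample_id", "group", "gene")]
  if (nrow(errors))
    errors$error <- sprintf("missing reference Ct ('%s')", reference_gene)
  m <- m[!is.na(m$ref_ct), , drop = FALSE]
  if (!nrow(m))
    stop("no sample has a reference-gene Ct", call. = FALSE)

  m$delta_ct <- m$ct - m$ref_ct
  # calibrate per gene against the arithmetic mean control-group dCt
  ctrl_mean <- tapply(m$delta_ct[m$group == control_group],
                      m$gene[m$group == control_group], mean)
  if (any(!(unique(m$gene) %in% names(ctrl_mean))))
    stop("control group has no samples for some gene(s)", call. = FALSE)
  m$delta_delta_ct <- m$delta_ct - unname(ctrl_mean[m$gene])
  m$fold_change <- 2^(-m$delta_delta_ct)

  samples <- m[order(m$gene, m$group, m$sample_id),
               c("sample_id", "group", "gene", "delta_ct",
                 "delta_delta_ct", "fold_change")]
  rownames(samples) <- NULL

  groups <- do.call(rbind, lapply(split(samples, samples[c("gene", "group")],
                                        drop = TRUE), function(d) {
    data.frame(group = d$group[1], gene = d$gene[1],
               mean_fold = mean(d$fold_change), sem_fold = sem(d$fold_change),
               mean_log2_fold = mean(log2(d$fold_change)),
               sem_log2_fold = sem(log2(d$fold_change)),
               n = nrow(d))
  }))
  groups <- groups[order(groups$gene, groups$group), , drop = FALSE]
  rownames(groups) <- NULL

  list(samples = samples, groups = groups, errors = errors)
}
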
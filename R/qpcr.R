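# qPCR relative quantification: per-plate delta-CT against a reference
# miRNA, per-sample aggregation, group comparison and 2^(-ddCT) fold
# changes.

#' Read / write a qPCR well table
#'
#' CSV with columns \code{sample}, \code{target}, \code{plate},
#' \code{replicate}, \code{ct}.
#'
#' @param path file path.
#' @return data.frame of wells.
#' @export
readQpcrWells <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("sample", "target", "plate", "replicate", "ct")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("well table lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' @rdname readQpcrWells
#' @param x well data.frame.
#' @export
writeQpcrWells <- function(x, path) {
  write.csv(x, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-plate and per-sample delta-CT against a reference target
#'
#' Within each (sample, plate), replicate CTs are averaged per target
#' and the reference's average CT is subtracted from each target's
#' average CT, giving one delta-CT per plate. Plates lacking the
#' reference for a sample are dropped with a warning; a sample with no
#' reference wells on any plate is an error. The per-sample delta-CT is
#' the unweighted mean of the per-plate values.
#'
#' @param wells well data.frame (see [readQpcrWells()]).
#' @param reference reference target id (the stably expressed
#'   normalizer, \code{"hsa-miR-423"} in the assay this package
#'   mirrors).
#' @return data.frame with columns \code{sample}, \code{target},
#'   \code{deltaCt}, \code{nPlates}; one row per (sample, target). The
#'   reference target itself appears with delta-CT exactly 0.
#' @examples
#' w <- data.frame(sample = "s1", target = rep(c("m1", "ref"), each = 2),
#'                 plate = 1, replicate = 1:2, ct = c(24.0, 24.2, 20, 20))
#' plateDeltaCt(w, reference = "ref")   # deltaCt 4.1
#' @export
plateDeltaCt <- function(wells, reference) {
  stopifnot(all(c("sample", "target", "plate", "replicate", "ct")
                %in% colnames(wells)))
  if (!reference %in% wells$target)
    stop("reference target '", reference, "' has no wells")
  if (any(!is.finite(wells$ct))) stop("CT values must be finite")
  # mean CT per (sample, target, plate)
  agg <- aggregate(ct ~ sample + target + plate, wells, mean)
  ref <- agg[agg$target == reference, c("sample", "plate", "ct")]
  names(ref)[3L] <- "refCt"
  tgt <- agg                             # the reference itself yields dCT 0
  for (smp in unique(tgt$sample)) {
    if (!smp %in% ref$sample)
      stop("no reference wells on any plate for sample '", smp, "'")
  }
  mrg <- merge(tgt, ref, by = c("sample", "plate"))
  dropped <- nrow(tgt) - nrow(mrg)
  if (dropped > 0L)
    warning(dropped, " (sample, target, plate) combination(s) dropped: ",
            "reference missing on that plate")
  mrg$dct <- mrg$ct - mrg$refCt
  out <- aggregate(dct ~ sample + target, mrg, mean)
  names(out)[3L] <- "deltaCt"
  np <- aggregate(plate ~ sample + target, mrg, function(p) length(unique(p)))
  names(np)[3L] <- "nPlates"
  merge(out, np, by = c("sample", "target"))
}

#' Fold change from a delta-delta-CT
#'
#' The standard relation: one PCR cycle is one doubling, so a
#' case-minus-control difference of delta-CTs maps to
#' \eqn{2^{-\Delta\Delta CT}}; negative ddCT (earlier amplification in
#' cases) means increased expression, fold > 1.
#'
#' @param deltaDeltaCt numeric, cycles.
#' @return positive fold change(s).
#' @examples
#' foldChange(-1)     # one cycle earlier: 2-fold up
#' foldChange(-1.47)  # ~2.77-fold
#' @export
foldChange <- function(deltaDeltaCt) {
  2^(-deltaDeltaCt)
}

#' Compare group delta-CT distributions for one target
#'
#' Two-sided two-sample t-test on the per-sample delta-CTs of a case
#' group against a control group, plus the fold change implied by the
#' group-mean difference.
#'
#' @param records delta-CT records from [plateDeltaCt()].
#' @param samples sample metadata data.frame (columns \code{sample},
#'   \code{group}).
#' @param target target miRNA id.
#' @param gCase,gControl group labels contrasted (case minus control).
#' @param varEqual use the pooled-variance Student's t-test (default);
#'   FALSE gives Welch.
#' @return one-row data.frame: \code{target}, \code{contrast},
#'   \code{meanCase}, \code{meanControl}, \code{deltaDeltaCt},
#'   \code{foldChange}, \code{p}, \code{nCase}, \code{nControl}.
#' @export
groupCompare <- function(records, samples, target, gCase, gControl,
                         varEqual = TRUE) {
  rec <- records[records$target == target, , drop = FALSE]
  grp <- samples$group[match(rec$sample, samples$sample)]
  dCase <- rec$deltaCt[grp %in% gCase]
  dCtrl <- rec$deltaCt[grp %in% gControl]
  if (length(dCase) < 2L || length(dCtrl) < 2L)
    stop("need at least 2 delta-CT records per group for target '",
         target, "'")
  tt <- t.test(dCase, dCtrl, var.equal = varEqual)
  ddct <- mean(dCase) - mean(dCtrl)
  data.frame(target = target,
             contrast = paste(gCase, "vs", gControl),
             meanCase = mean(dCase), meanControl = mean(dCtrl),
             deltaDeltaCt = ddct, foldChange = foldChange(ddct),
             p = tt$p.value, nCase = length(dCase),
             nControl = length(dCtrl), stringsAsFactors = FALSE)
}

#' Validation summary across targets and contrasts
#'
#' One row per target with the t-test p-value per contrast and the fold
#' change where significant (blank otherwise), mirroring how qPCR
#' validation outcomes are conventionally reported.
#'
#' @param records delta-CT records from [plateDeltaCt()].
#' @param samples sample metadata (columns \code{sample}, \code{group}).
#' @param targets targets to report.
#' @param contrasts list of c(case, control) label pairs.
#' @param alpha significance level gating the fold-change column
#'   (default 0.05).
#' @param varEqual see [groupCompare()].
#' @return data.frame with, per contrast, columns \code{p <case>} and
#'   \code{fold <case>} (empty string when not significant).
#' @export
qpcrSummary <- function(records, samples, targets, contrasts,
                        alpha = 0.05, varEqual = TRUE) {
  out <- data.frame(miRNA = targets, stringsAsFactors = FALSE)
  for (ct in contrasts) {
    pcol <- paste0("p ", ct[1L])
    fcol <- paste0("fold ", ct[1L])
    ps <- numeric(length(targets))
    fc <- character(length(targets))
    for (i in seq_along(targets)) {
      g <- groupCompare(records, samples, targets[i], ct[1L], ct[2L],
                        varEqual = varEqual)
      ps[i] <- g$p
      fc[i] <- if (g$p < alpha) format(round(g$foldChange, 2L)) else ""
    }
    out[[pcol]] <- ps
    out[[fcol]] <- fc
  }
  out
}

#' @rdname qpcrSummary
#' @param x summary data.frame.
#' @param path output TSV path.
#' @export
writeQpcrSummary <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
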
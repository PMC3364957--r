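## RT-qPCR normalization: reference-gene fold changes with SEM and Welch p,
## composable normalization chains for IP experiments, and the significance
## star annotation.

#' Reference-normalized fold change of a gene between conditions
#'
#' Per replicate, the gene's quantity is divided by the reference gene's
#' quantity in the same sample; condition ratios are then expressed relative
#' to the mean baseline ratio.  The mean, the SEM over biological
#' replicates, and a Welch t test against the baseline ratios are reported,
#' matching bar-plot summaries with SEM error bars.
#'
#' @param q long data.frame: sample_id, genotype, replicate, gene_id,
#'   quantity (positive).
#' @param gene gene of interest.
#' @param reference_gene reference mRNA (default `tbb-2`).
#' @param condition genotype whose change is reported.
#' @param baseline baseline genotype (default wild type).
#' @return list with `fold`, `sem`, `p`, `stars`, `n`, and the
#'   per-replicate ratios of both conditions.
#' @export
reference_fold_change <- function(q, gene, reference_gene = "tbb-2",
                                  condition, baseline = "wt") {
  ratios <- function(geno) {
    sub <- q[q$genotype == geno, , drop = FALSE]
    g <- sub[sub$gene_id == gene, ]
    r <- sub[sub$gene_id == reference_gene, ]
    m <- merge(g, r, by = "replicate", suffixes = c("_gene", "_ref"))
    if (!nrow(m)) {
      stop("gene and reference not both measured in ", geno, call. = FALSE)
    }
    if (any(m$quantity_ref <= 0)) {
      stop("reference quantities must be positive", call. = FALSE)
    }
    setNames(m$quantity_gene / m$quantity_ref, m$replicate)
  }
  r_cond <- ratios(condition)
  r_base <- ratios(baseline)
  rel_cond <- r_cond / mean(r_base)
  rel_base <- r_base / mean(r_base)
  fold <- mean(rel_cond)
  sem <- sd(rel_cond) / sqrt(length(rel_cond))
  p <- tryCatch(t.test(rel_cond, rel_base, var.equal = FALSE)$p.value,
                error = function(e) {
                  # degenerate noiseless case: both groups constant
                  if (isTRUE(all.equal(fold, mean(rel_base)))) 1 else 0
                })
  list(fold = fold, sem = sem, p = p, stars = significance_stars(p),
       n = length(rel_cond), ratios_condition = rel_cond,
       ratios_baseline = rel_base)
}

#' Normalization chain steps
#'
#' A chain is an ordered list of division steps applied left to right.
#' `norm_step_gene(g)` divides every quantity by the same sample's value of
#' reference gene `g`; `norm_step_class(a)` divides every quantity by the
#' same gene's value in the matched sample (same genotype and replicate) of
#' assay class `a` (e.g. control_ip, input).
#'
#' @param gene,assay the reference of the step.
#' @return a step object for [apply_chain()].
#' @export
norm_step_gene <- function(gene) {
  structure(list(type = "gene", ref = gene), class = "polystab_norm_step")
}

#' @rdname norm_step_gene
#' @export
norm_step_class <- function(assay) {
  structure(list(type = "class", ref = assay), class = "polystab_norm_step")
}

#' Apply a normalization chain to qPCR quantities
#'
#' Steps are successive divisions, so independent steps commute.  Reference
#' values are taken from the working table, i.e. they have been through the
#' preceding steps themselves; as a consequence the canonical IP chain
#' `list(norm_step_class("control_ip"), norm_step_class("input"),
#' norm_step_gene("tbb-2"))` -- normalize to the control IP, then to input
#' mRNA levels, and finally to the reference mRNA -- cancels both the
#' per-gene input abundance and every per-sample nuisance scale factor, and
#' on noiseless data returns exactly the planted IP enrichment.
#'
#' @param q long data.frame: sample_id, assay, genotype, replicate, gene_id,
#'   quantity.
#' @param chain list of steps from [norm_step_gene()] /
#'   [norm_step_class()].
#' @param keep_assay assay whose normalized values are returned (default
#'   `"ip"` when present, otherwise all rows).
#' @return data.frame: assay, genotype, replicate, gene_id, value.
#' @export
apply_chain <- function(q, chain, keep_assay = NULL) {
  if (!length(chain)) stop("empty normalization chain", call. = FALSE)
  work <- q
  work$value <- work$quantity
  for (i in seq_along(chain)) {
    step <- chain[[i]]
    stopifnot(inherits(step, "polystab_norm_step"))
    if (step$type == "gene") {
      ref <- work[work$gene_id == step$ref,
                  c("sample_id", "value"), drop = FALSE]
      names(ref)[2] <- "ref_value"
      merged <- merge(work, ref, by = "sample_id", all.x = TRUE)
    } else {
      ref <- work[work$assay == step$ref,
                  c("genotype", "replicate", "gene_id", "value")]
      names(ref)[4] <- "ref_value"
      merged <- merge(work, ref, by = c("genotype", "replicate", "gene_id"),
                      all.x = TRUE)
    }
    if (anyNA(merged$ref_value)) {
      stop(sprintf("normalization chain step %d (%s '%s'): reference missing",
                   i, step$type, step$ref), call. = FALSE)
    }
    merged$value <- merged$value / merged$ref_value
    merged$ref_value <- NULL
    work <- merged
  }
  if (is.null(keep_assay)) {
    keep_assay <- if ("ip" %in% work$assay) "ip" else unique(work$assay)
  }
  out <- work[work$assay %in% keep_assay,
              c("assay", "genotype", "replicate", "gene_id", "value")]
  out <- out[order(out$assay, out$genotype, out$replicate, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Significance stars for a p value
#'
#' `***` if p < 0.001, `**` if p < 0.01, `*` if p < 0.05, otherwise empty;
#' all inequalities strict (p = 0.05 earns no star).
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return character vector of star annotations.
#' @export
significance_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Fold-change table for a panel of genes
#'
#' Runs [reference_fold_change()] for each gene and condition and returns a
#' tidy results table with fold, SEM, Welch p and stars.
#'
#' @param q long qPCR quantity table.
#' @param genes genes to report.
#' @param conditions genotypes to compare against the baseline.
#' @param reference_gene,baseline as in [reference_fold_change()].
#' @return data.frame: gene_id, condition, fold, sem, p, stars, n.
#' @export
qpcr_fold_change_table <- function(q, genes, conditions,
                                   reference_gene = "tbb-2",
                                   baseline = "wt") {
  rows <- expand.grid(gene_id = genes, condition = conditions,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    fc <- reference_fold_change(q, rows$gene_id[i],
                                reference_gene = reference_gene,
                                condition = rows$condition[i],
                                baseline = baseline)
    data.frame(gene_id = rows$gene_id[i], condition = rows$condition[i],
               fold = fc$fold, sem = fc$sem, p = fc$p, stars = fc$stars,
               n = fc$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
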
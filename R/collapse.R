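#' Qualify annotated variants under a collapsing model
#'
#' Applies the qualifying-variant rule to an annotated variant table: the
#' consequence must belong to the model's consequence set (`"coding"`:
#' stop_lost, missense_variant, start_lost, splice_donor_variant,
#' inframe_deletion, frameshift_variant, splice_acceptor_variant, stop_gained,
#' inframe_insertion; `"lof"`: the loss-of-function subset), the variant must
#' not be predicted benign (PolyPhen benign is < 0.15, SIFT benign is > 0.05;
#' missing scores are never benign), and its allele frequency must be below
#' `maf_max` in every gnomAD population and locally.
#'
#' @param variants Tibble with columns `variant_id`, `gene_id`, `consequence`,
#'   `polyphen_score`, `sift_score`, `local_af`, and one or more
#'   `gnomad_af_*` columns. Missing gnomAD frequencies count as 0.
#' @param model `"coding"` or `"lof"`.
#' @param thresholds A [screen_thresholds()] (or list of overrides).
#' @return The input tibble with a logical `qualifying` column appended.
#' @examples
#' v <- tibble::tibble(variant_id = "chr1:1:A:G", gene_id = "G1",
#'                     consequence = "missense_variant", polyphen_score = 0.9,
#'                     sift_score = 0.01, local_af = 5e-4,
#'                     gnomad_af_nfe = 5e-4, carriers = "S1")
#' qualify_variants(v, "coding")$qualifying
#' @export
qualify_variants <- function(variants, model = "coding", thresholds = NULL) {
  t <- as_thresholds(thresholds)
  model <- check_model(model)
  req <- c("gene_id", "consequence", "polyphen_score", "sift_score", "local_af")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L) {
    abort(paste("variant table lacks column(s):", paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(unique(variants$consequence), consequence_vocabulary())
  if (length(unknown) > 0L) {
    abort(paste("unknown consequence term(s):", paste(unknown, collapse = ", ")))
  }
  gcols <- grep("^gnomad_af_", names(variants), value = TRUE)
  freqs <- as.matrix(variants[, c(gcols, "local_af")])
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  freqs[is.na(freqs)] <- 0   # absent population frequency: no evidence of commonness
  max_af <- apply(freqs, 1L, max)

  cons_ok <- variants$consequence %in% model_consequences(model)
  poly_benign <- !is.na(variants$polyphen_score) &
    variants$polyphen_score < t$polyphen_benign_below
  sift_benign <- !is.na(variants$sift_score) &
    variants$sift_score > t$sift_benign_above
  benign <- if (t$benign_rule == "either") {
    poly_benign | sift_benign
  } else {
    poly_benign & sift_benign
  }
  dplyr::mutate(variants,
                qualifying = cons_ok & !benign & max_af < t$maf_max)
}

#' Qualify CNV events under a collapsing model
#'
#' A CNV event qualifies when it carries the PASS QC flag, both its exon-level
#' and event-level within-cohort frequencies are below `cnv_freq_max`, and its
#' type fits the model: deletions overlapping at least one exon for the LoF
#' model; deletions or duplications for the coding (damaging) model.
#'
#' @param cnvs Tibble with columns `sample_id`, `gene_id`, `cnv_type`
#'   (`"deletion"` or `"duplication"`), `n_exons_overlapped`, `qc_pass`,
#'   `exon_freq`, `event_freq`.
#' @inheritParams qualify_variants
#' @return The input tibble with a logical `qualifying` column appended.
#' @export
qualify_cnvs <- function(cnvs, model = "coding", thresholds = NULL) {
  t <- as_thresholds(thresholds)
  model <- check_model(model)
  if (nrow(cnvs) == 0L) return(dplyr::mutate(cnvs, qualifying = logical(0)))
  if (any(cnvs$n_exons_overlapped < 0)) abort("negative exon count")
  if (any(is.na(cnvs$qc_pass))) abort("QC status must be known for every CNV")
  bad <- c(cnvs$exon_freq, cnvs$event_freq)
  if (any(is.na(bad) | bad < 0 | bad > 1)) {
    abort("CNV frequencies must lie in [0, 1]")
  }
  type_ok <- if (model == "lof") {
    cnvs$cnv_type == "deletion" & cnvs$n_exons_overlapped >= 1L
  } else {
    cnvs$cnv_type %in% c("deletion", "duplication")
  }
  dplyr::mutate(cnvs,
                qualifying = .data$qc_pass &
                  .data$exon_freq < t$cnv_freq_max &
                  .data$event_freq < t$cnv_freq_max & type_ok)
}

#' Collapse qualifying variants and CNVs into a gene burden matrix
#'
#' Codes each sample 1 for a gene if it carries at least one qualifying
#' variant or qualifying CNV in that gene under the model, 0 otherwise. Genes
#' with zero qualifying carriers are retained as all-zero columns.
#'
#' @param variants Annotated variant tibble (see [qualify_variants()]) with a
#'   `carriers` column of comma-separated sample ids.
#' @param samples Sample manifest tibble with a `sample_id` column; fixes the
#'   sample universe (rows of the matrix).
#' @param cnvs Optional CNV tibble (see [qualify_cnvs()]); `NULL` for cohorts
#'   whose platform calls no CNVs.
#' @param genes Optional character vector fixing the gene universe; defaults
#'   to all genes seen in `variants` and `cnvs`.
#' @inheritParams qualify_variants
#' @return An object of class `burden_matrix`: integer samples-by-genes 0/1
#'   matrix with the model name and per-gene carrier counts attached. Use
#'   [tidy.burden_matrix()] for a long tibble.
#' @export
collapse_burden <- function(variants, samples, cnvs = NULL, model = "coding",
                            thresholds = NULL, genes = NULL) {
  t <- as_thresholds(thresholds)
  model <- check_model(model)
  sample_ids <- samples$sample_id
  if (anyDuplicated(sample_ids)) abort("duplicate sample_id in manifest")

  qv <- dplyr::filter(qualify_variants(variants, model, t), .data$qualifying)
  pairs <- carrier_pairs(qv)
  if (!is.null(cnvs) && nrow(cnvs) > 0L) {
    qc <- dplyr::filter(qualify_cnvs(cnvs, model, t), .data$qualifying)
    pairs <- dplyr::bind_rows(pairs, qc[, c("gene_id", "sample_id")])
  }
  unknown <- setdiff(pairs$sample_id, sample_ids)
  if (length(unknown) > 0L) {
    abort(paste("carrier sample(s) absent from manifest:",
                paste(head(unknown, 5L), collapse = ", ")))
  }
  if (is.null(genes)) {
    genes <- sort(unique(c(variants$gene_id,
                           if (!is.null(cnvs)) cnvs$gene_id)))
  }
  m <- matrix(0L, nrow = length(sample_ids), ncol = length(genes),
              dimnames = list(sample_ids, genes))
  pairs <- dplyr::filter(pairs, .data$gene_id %in% genes)
  if (nrow(pairs) > 0L) {
    m[cbind(match(pairs$sample_id, sample_ids),
            match(pairs$gene_id, genes))] <- 1L
  }
  structure(m, class = c("burden_matrix", "matrix", "array"), model = model)
}

carrier_pairs <- function(variant_rows) {
  if (nrow(variant_rows) == 0L) {
    return(tibble::tibble(gene_id = character(), sample_id = character()))
  }
  lst <- strsplit(variant_rows$carriers, ",", fixed = TRUE)
  out <- tibble::tibble(
    gene_id = rep(variant_rows$gene_id, lengths(lst)),
    sample_id = unlist(lst, use.names = FALSE))
  dplyr::distinct(dplyr::filter(out, nzchar(.data$sample_id)))
}

#' Per-gene carrier counts of a burden matrix
#' @param x A `burden_matrix`.
#' @return Named integer vector (column sums).
#' @export
carrier_counts <- function(x) {
  stopifnot(inherits(x, "burden_matrix"))
  colSums(unclass(x))
}

#' @export
print.burden_matrix <- function(x, ...) {
  cat(sprintf("<burden_matrix> model=%s, %d samples x %d genes, %d carrier entries\n",
              attr(x, "model"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Tidy a burden matrix into a long carrier tibble
#'
#' @param x A `burden_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `gene_id`, `carrier` (only rows
#'   with `carrier == 1`).
#' @export
tidy.burden_matrix <- function(x, ...) {
  idx <- which(unclass(x) == 1L, arr.ind = TRUE)
  tibble::tibble(sample_id = rownames(x)[idx[, 1L]],
                 gene_id = colnames(x)[idx[, 2L]],
                 carrier = 1L) |>
    dplyr::arrange(.data$gene_id, .data$sample_id)
}
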
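#' Gene-by-library count table
#'
#' Container for CDS read counts per gene and sequencing library, together
#' with the design description of each library (library type, replicate,
#' tissue).
#'
#' @param counts integer matrix, genes in rows, libraries in columns.
#' @param design data frame with one row per column of `counts` and columns
#'   `sample`, `library` ("Ribo"/"RNA"), `replicate`, `tissue`.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, design) {
  counts <- as.matrix(counts)
  stopifnot(nrow(design) == ncol(counts),
            all(c("sample", "library", "replicate", "tissue") %in% names(design)),
            all(design$library %in% c("Ribo", "RNA")))
  if (any(counts < 0)) stop("counts must be non-negative")
  colnames(counts) <- design$sample
  structure(list(counts = counts, design = as.data.frame(design)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d genes x %d libraries (%d Ribo, %d RNA; tissues: %s)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$design$library == "Ribo"), sum(x$design$library == "RNA"),
              paste(unique(x$design$tissue), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' A-site offset from fragment length
#'
#' Length-dependent offset of the ribosomal A-site from the 5' end of a
#' ribosome-protected fragment: +14 nt for fragments of 29 nt or shorter,
#' +15 for 30-31 nt, +16 for 32-35 nt and +17 for 36 nt or longer.
#'
#' @param length integer vector of fragment lengths (nt, >= 1).
#' @return integer vector of offsets.
#' @export
asite_offset <- function(length) {
  stopifnot(all(length >= 1))
  ifelse(length <= 29L, 14L,
         ifelse(length <= 31L, 15L,
                ifelse(length <= 35L, 16L, 17L)))
}

#' Assign A-site positions to fragments
#'
#' Adds an `asite` column (`pos5 + asite_offset(length)`, 0-based transcript
#' coordinate). The same length-based rule is applied to both library types
#' so that Ribo and RNA reads are processed identically for counting.
#' Fragments whose A-site falls outside the transcript are dropped; the
#' number dropped is recorded in `attr(,"n_dropped")`.
#'
#' @param fragments fragment data frame (`transcript_id`, `pos5`, `length`,
#'   ...).
#' @param transcripts a [transcript_set].
#' @return the fragments that remain, with an `asite` column.
#' @export
assign_asite <- function(fragments, transcripts) {
  i <- match(fragments$transcript_id, transcripts$gene_id)
  if (anyNA(i)) stop("fragments refer to unknown transcripts")
  asite <- fragments$pos5 + asite_offset(fragments$length)
  ok <- asite >= 0L & asite < tx_length(transcripts)[i]
  out <- fragments[ok, , drop = FALSE]
  out$asite <- as.integer(asite[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Codon-masked CDS count for one transcript
#'
#' Counts assigned positions falling in the CDS after excluding the first
#' `mask_start_codons` and last `mask_end_codons` codons (defaults 15 and 5,
#' masking the start-proximal pileup and the terminating region). With the
#' defaults, counted positions `p` satisfy
#' `cds_start + 45 <= p < cds_end - 15`.
#'
#' @param positions integer vector of assigned (A-site) 0-based transcript
#'   positions.
#' @param utr5_len,cds_len region lengths of the transcript.
#' @param mask_start_codons,mask_end_codons codons excluded at either end.
#' @return integer count, or `NA` (with a warning) when the CDS is too short
#'   for the mask.
#' @export
count_cds <- function(positions, utr5_len, cds_len,
                      mask_start_codons = 15L, mask_end_codons = 5L) {
  if (cds_len <= 3L * (mask_start_codons + mask_end_codons)) {
    warning("CDS too short for the codon mask; gene excluded")
    return(NA_integer_)
  }
  lo <- utr5_len + 3L * mask_start_codons
  hi <- utr5_len + cds_len - 3L * mask_end_codons
  sum(positions >= lo & positions < hi)
}

#' Build the gene-by-library count table from fragments
#'
#' Assigns every fragment an A-site by the length-offset rule (applied to
#' both Ribo and RNA libraries), then counts A-sites in the codon-masked CDS
#' window per gene and library. Genes whose CDS is too short for the mask
#' are excluded (recorded in `attr(,"excluded_genes")`).
#'
#' @inheritParams assign_asite
#' @inheritParams count_cds
#' @return a [count_table]; libraries are the distinct
#'   (library, replicate, tissue) combinations present in `fragments`.
#' @export
build_count_table <- function(fragments, transcripts,
                              mask_start_codons = 15L, mask_end_codons = 5L) {
  ok <- transcripts$cds_len > 3L * (mask_start_codons + mask_end_codons)
  excluded <- transcripts$gene_id[!ok]
  if (length(excluded))
    message(sprintf("%d gene(s) excluded: CDS too short for the codon mask",
                    length(excluded)))
  ts <- transcripts[ok, , drop = FALSE]
  design <- unique(fragments[, c("library", "replicate", "tissue"),
                             drop = FALSE])
  design <- design[order(design$tissue, design$library, design$replicate), ,
                   drop = FALSE]
  design$sample <- paste(design$tissue, design$library, design$replicate,
                         sep = "_")
  rownames(design) <- NULL
  K <- matrix(0L, nrow(ts), nrow(design),
              dimnames = list(ts$gene_id, design$sample))
  if (nrow(fragments)) {
    fr <- assign_asite(fragments, transcripts)
    fr <- fr[fr$transcript_id %in% ts$gene_id, , drop = FALSE]
    i <- match(fr$transcript_id, ts$gene_id)
    lo <- ts$utr5_len[i] + 3L * mask_start_codons
    hi <- ts$utr5_len[i] + ts$cds_len[i] - 3L * mask_end_codons
    inwin <- fr$asite >= lo & fr$asite < hi
    fr <- fr[inwin, , drop = FALSE]
    if (nrow(fr)) {
      samp <- paste(fr$tissue, fr$library, fr$replicate, sep = "_")
      tab <- table(factor(fr$transcript_id, levels = ts$gene_id),
                   factor(samp, levels = design$sample))
      K <- matrix(as.integer(tab), nrow(ts), nrow(design),
                  dimnames = dimnames(K))
    }
  }
  ct <- count_table(K, design[, c("sample", "library", "replicate", "tissue")])
  attr(ct, "excluded_genes") <- excluded
  ct
}

#' Write / read a count table as TSV (+ JSON design sidecar)
#'
#' @param ct a [count_table].
#' @param tsv path for the genes-by-libraries matrix.
#' @param json path for the design description.
#' @return paths invisibly / a [count_table].
#' @export
write_count_table <- function(ct, tsv, json) {
  df <- data.frame(gene_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ct$design, json, dataframe = "rows")
  invisible(c(tsv = tsv, json = json))
}

#' @rdname write_count_table
#' @export
read_count_table <- function(tsv, json) {
  df <- utils::read.delim(tsv, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$gene_id
  design <- jsonlite::read_json(json, simplifyVector = TRUE)
  count_table(K, design)
}
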
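#' Near-cognate start codons
#'
#' The nine codons one substitution away from ATG, the accepted candidate
#' set for non-canonical initiation.
#'
#' @return character vector of codons (DNA alphabet).
#' @export
near_cognate_codons <- function() {
  c("CTG", "GTG", "TTG", "ACG", "AGG", "AAG", "ATA", "ATC", "ATT")
}

normalize_nt <- function(x, what = "sequence") {
  x <- toupper(gsub("U", "T", x, fixed = TRUE))
  if (grepl("[^ACGT]", x))
    stop(sprintf("%s contains non-nucleotide characters", what))
  x
}

#' Kozak-context favourability of a start codon
#'
#' The default (`convention = "adjacent"`) tests the context positions as
#' numbered with the codon occupying 0-2: favourable iff the nucleotide
#' immediately 5' of the codon (-1) is G and the first nucleotide after the
#' codon (+3) is A or G. `convention = "classical"` instead applies the
#' classical Kozak numbering (A of AUG = +1): A/G three nucleotides before
#' the codon and G immediately after it. Missing context (codon at a
#' sequence edge) is never favourable.
#'
#' @param seq full nucleotide sequence containing the codon.
#' @param position 0-based start of the codon within `seq`.
#' @param convention `"adjacent"` (default) or `"classical"`.
#' @return logical.
#' @export
kozak_favourable <- function(seq, position,
                             convention = c("adjacent", "classical")) {
  convention <- match.arg(convention)
  seq <- normalize_nt(seq)
  p <- position + 1L  # 1-based codon start
  at <- function(i) if (i >= 1L && i <= nchar(seq)) substr(seq, i, i) else ""
  if (convention == "adjacent") {
    at(p - 1L) == "G" && at(p + 3L) %in% c("A", "G")
  } else {
    at(p - 3L) %in% c("A", "G") && at(p + 3L) == "G"
  }
}

# scan in-frame triplets from `from` (0-based, within utr+cds paste);
# returns list(stop_position (0-based or NA), class, in_frame)
scan_orf <- function(full, from, utr_len) {
  n <- nchar(full)
  q <- from
  stop_pos <- NA_integer_
  while (q + 3L <= n) {
    cod <- substr(full, q + 1L, q + 3L)
    if (cod %in% STOP_CODONS) { stop_pos <- q; break }
    q <- q + 3L
  }
  frame0 <- ((utr_len - from) %% 3L) == 0L
  if (!is.na(stop_pos) && stop_pos < utr_len) {
    cls <- "uORF"
  } else if (frame0) {
    cls <- "in-frame-extension"
  } else {
    cls <- "oORF"
  }
  list(stop_position = stop_pos, orf_class = cls, in_frame = frame0)
}

#' Scan a 5'UTR for upstream initiation sites
#'
#' Reports every AUG in the 5'UTR (any context) and, when
#' `near_cognate = TRUE`, every near-cognate codon (one substitution from
#' AUG) in a favourable Kozak context. Each site is classified by
#' translating in-frame triplets until the first stop codon (UAA/UAG/UGA),
#' continuing into the CDS when no stop occurs in the UTR:
#' a stop upstream of the CDS start makes the site a uORF; no upstream stop
#' and a nonzero frame offset against the main ORF makes it an oORF
#' (overlapping the CDS out of frame); frame offset zero is an in-frame
#' extension of the main ORF.
#'
#' @param utr,cds nucleotide strings (T or U); `cds` must begin with AUG.
#' @param near_cognate include near-cognate sites (default TRUE).
#' @param convention Kozak convention, see [kozak_favourable()].
#' @param codons candidate near-cognate codon set.
#' @return data frame of class `start_sites`: `position` (0-based offset in
#'   the UTR), `codon`, `canonical`, `kozak_favourable`, `orf_class`,
#'   `stop_position` (0-based, `NA` if no stop before the sequence end),
#'   `in_frame_with_main`.
#' @export
find_start_sites <- function(utr, cds, near_cognate = TRUE,
                             convention = c("adjacent", "classical"),
                             codons = near_cognate_codons()) {
  convention <- match.arg(convention)
  utr <- normalize_nt(utr, "utr")
  cds <- normalize_nt(cds, "cds")
  if (nchar(cds) < 3L || substr(cds, 1L, 3L) != "ATG")
    stop("cds must start with ATG")
  full <- paste0(utr, cds)
  ulen <- nchar(utr)
  empty <- data.frame(position = integer(), codon = character(),
                      canonical = logical(), kozak_favourable = logical(),
                      orf_class = character(), stop_position = integer(),
                      in_frame_with_main = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("start_sites", "data.frame")
  if (ulen < 3L) return(empty)
  pos <- 0:(ulen - 3L)
  cod <- substring(full, pos + 1L, pos + 3L)
  canonical <- cod == "ATG"
  kz <- vapply(pos, function(p) kozak_favourable(full, p, convention),
               logical(1))
  keep <- canonical | (near_cognate & cod %in% codons & kz)
  if (!any(keep)) return(empty)
  pos <- pos[keep]; cod <- cod[keep]
  canonical <- canonical[keep]; kz <- kz[keep]
  orf <- lapply(pos, function(p) scan_orf(full, p, ulen))
  out <- data.frame(position = pos, codon = cod, canonical = canonical,
                    kozak_favourable = kz,
                    orf_class = vapply(orf, `[[`, character(1), "orf_class"),
                    stop_position = vapply(orf, `[[`, integer(1),
                                           "stop_position"),
                    in_frame_with_main = vapply(orf, `[[`, logical(1),
                                                "in_frame"),
                    stringsAsFactors = FALSE)
  class(out) <- c("start_sites", "data.frame")
  out
}

#' @export
print.start_sites <- function(x, ...) {
  cat(sprintf("start_sites: %d upstream site(s) (%d uAUG, %d near-cognate)\n",
              nrow(x), sum(x$canonical), sum(!x$canonical)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Classify the ORF initiated at an upstream site
#'
#' @param position 0-based codon start within the UTR.
#' @inheritParams find_start_sites
#' @return list with `orf_class`, `stop_position`, `in_frame_with_main`.
#' @export
classify_orf <- function(position, utr, cds, ...) {
  utr <- normalize_nt(utr, "utr")
  cds <- normalize_nt(cds, "cds")
  stopifnot(position >= 0, position <= nchar(utr) - 3L)
  r <- scan_orf(paste0(utr, cds), position, nchar(utr))
  list(orf_class = r$orf_class, stop_position = r$stop_position,
       in_frame_with_main = r$in_frame)
}

#' Mutation specification for in-silico 5'UTR mutagenesis
#'
#' The three mutagenesis operations used to dissect uORF function:
#' `start_point_mutation` replaces an upstream start codon (canonically with
#' AAG or CAG); `stop_point_mutation` substitutes bases in place (e.g.
#' disrupting ugUGA to ugAGA); `insertion` inserts bases (C or CC just
#' before the main CDS shifts upstream frames by +1/+2).
#'
#' @param kind one of `"start_point_mutation"`, `"stop_point_mutation"`,
#'   `"insertion"`.
#' @param position 0-based position in the 5'UTR: codon start for start
#'   mutations, first replaced base for stop mutations, insertion point for
#'   insertions (`nchar(utr)` inserts just before the CDS).
#' @param bases replacement or inserted bases.
#' @return a `mutation_spec` list.
#' @export
mutation_spec <- function(kind = c("start_point_mutation",
                                   "stop_point_mutation", "insertion"),
                          position, bases) {
  kind <- match.arg(kind)
  bases <- normalize_nt(bases, "bases")
  if (kind == "start_point_mutation" && !bases %in% c("AAG", "CAG"))
    warning("start codons are canonically mutated to AAG or CAG")
  structure(list(kind = kind, position = as.integer(position), bases = bases),
            class = "mutation_spec")
}

#' Apply a mutation to a 5'UTR and re-annotate
#'
#' Applies a [mutation_spec()] to the UTR and reruns [find_start_sites()].
#' Replacements that create a new AUG are allowed but flagged.
#'
#' @inheritParams find_start_sites
#' @param spec a [mutation_spec()].
#' @return list with `utr` (mutated), `cds`, `sites` (re-annotation), and
#'   `new_aug_created` (logical flag).
#' @export
apply_mutation <- function(utr, cds, spec, ...) {
  stopifnot(inherits(spec, "mutation_spec"))
  utr <- normalize_nt(utr, "utr")
  before <- find_start_sites(utr, cds, ...)
  p <- spec$position
  if (spec$kind == "insertion") {
    if (p < 0L || p > nchar(utr)) stop("insertion position outside the UTR")
    mut <- paste0(substr(utr, 1L, p), spec$bases,
                  substr(utr, p + 1L, nchar(utr)))
  } else {
    k <- nchar(spec$bases)
    if (p < 0L || p + k > nchar(utr)) stop("mutation runs outside the UTR")
    if (spec$kind == "start_point_mutation" &&
        substr(utr, p + 1L, p + 3L) != "ATG" &&
        !substr(utr, p + 1L, p + 3L) %in% near_cognate_codons())
      warning("start_point_mutation at a position that is not a start codon")
    mut <- utr
    substr(mut, p + 1L, p + k) <- spec$bases
  }
  sites <- find_start_sites(mut, cds, ...)
  before_can <- before$position[before$canonical]
  if (spec$kind == "insertion")
    before_can <- ifelse(before_can >= p, before_can + nchar(spec$bases),
                         before_can)
  new_aug <- any(!sites$position[sites$canonical] %in% before_can)
  list(utr = mut, cds = normalize_nt(cds, "cds"), sites = sites,
       new_aug_created = isTRUE(new_aug))
}

#' Descriptive clustering of upstream AUGs
#'
#' Groups uAUG positions into clusters separated by at least `gap` nt, a
#' descriptive aid for choosing deletion boundaries; no statistical model.
#'
#' @param positions sorted 0-based uAUG positions.
#' @param gap minimum separation between clusters (default 50 nt).
#' @return integer cluster index per position.
#' @export
cluster_uaugs <- function(positions, gap = 50L) {
  if (!length(positions)) return(integer(0))
  positions <- sort(positions)
  cumsum(c(1L, diff(positions) >= gap))
}
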
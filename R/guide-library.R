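#' Read / write a guide library TSV
#'
#' A guide library has columns `guide_id`, `gene_id`, `category` (one of
#' `gene`, `safe`, `nontargeting`) and optionally `protospacer` (uppercase
#' ACGT). Round-trips losslessly through [write_guide_library()].
#'
#' @param path TSV file path.
#' @return data.frame of class `guide_library`.
#' @export
read_guide_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_guide_library(df)
}

#' @rdname read_guide_library
#' @param lib a guide library data.frame.
#' @export
write_guide_library <- function(lib, path) {
  lib <- validate_guide_library(lib)
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_guide_library <- function(df) {
  req <- c("guide_id", "gene_id", "category")
  if (!all(req %in% names(df)))
    stop("guide library must have columns guide_id, gene_id, category")
  dup <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup))
    stop("duplicate guide_id in library: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$category), c("gene", "safe", "nontargeting"))
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  if ("protospacer" %in% names(df)) {
    ok <- grepl("^[ACGT]+$", df$protospacer)
    if (!all(ok))
      stop("protospacers must be uppercase ACGT; offending guide: ",
           paste(df$guide_id[!ok][1], collapse = ", "))
  }
  class(df) <- c("guide_library", "data.frame")
  df
}

#' Count guides in raw reads by anchored exact matching
#'
#' Each read is scanned for the constant vector `anchor`; the substring of
#' protospacer length that follows the first anchor occurrence is matched
#' exactly (0 mismatches) against the library. Reads without an anchor or
#' without an exact protospacer match are tallied as unmatched, so
#' `sum(counts) + unmatched == total`.
#'
#' @param reads path to a FASTQ file (gz accepted) or a character vector of
#'   read sequences.
#' @param lib a guide library with a `protospacer` column; protospacers must
#'   be unique.
#' @param anchor constant sequence immediately 5' of the protospacer.
#' @return List with `counts` (named integer vector over all library guides),
#'   `unmatched`, and `total`.
#' @export
count_guides_from_reads <- function(reads, lib, anchor) {
  lib <- validate_guide_library(as.data.frame(lib))
  if (!"protospacer" %in% names(lib))
    stop("library must contain protospacer sequences for read counting")
  if (anyDuplicated(lib$protospacer))
    stop("ambiguous library: duplicated protospacers cannot be counted")
  if (!grepl("^[ACGT]+$", anchor)) stop("anchor must be uppercase ACGT")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  reads <- toupper(as.character(reads))
  total <- length(reads)
  counts <- stats::setNames(integer(nrow(lib)), lib$guide_id)
  pos <- regexpr(anchor, reads, fixed = TRUE)
  has_anchor <- pos > 0L
  start <- pos[has_anchor] + nchar(anchor)
  seqs <- reads[has_anchor]
  matched <- rep(NA_integer_, length(seqs))
  # protospacer lengths may vary; try longer matches first
  for (len in sort(unique(nchar(lib$protospacer)), decreasing = TRUE)) {
    idx_len <- which(nchar(lib$protospacer) == len)
    lut <- stats::setNames(idx_len, lib$protospacer[idx_len])
    cand <- substr(seqs, start, start + len - 1L)
    hit <- lut[cand]
    take <- is.na(matched) & !is.na(hit)
    matched[take] <- hit[take]
  }
  tab <- table(factor(matched, levels = seq_len(nrow(lib))))
  counts[] <- as.integer(tab)
  unmatched <- total - sum(counts)
  list(counts = counts, unmatched = unmatched, total = total)
}
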
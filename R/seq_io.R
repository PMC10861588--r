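# Reading, validating and translating coding sequences.

#' Construct a gene record from a coding sequence
#'
#' Normalises a nucleotide string (upper case, RNA U mapped to T), splits it
#' into codons and drops codons containing characters outside A/C/G/T
#' (recording how many were dropped). A trailing 1-2 nt remainder is trimmed
#' with a warning.
#'
#' @param gene_id character label for the gene.
#' @param sequence DNA (or RNA) string.
#' @return An object of class `gene_record`: a list with elements `gene_id`,
#'   `sequence` (normalised input), `codons` (clean 3-mers), `length_nt`
#'   (3 x number of clean codons) and `ambiguous_codons_dropped`.
#' @examples
#' gene_record("BDNF", "ATGAAATAA")
#' @export
gene_record <- function(gene_id, sequence) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  seq <- chartr("u", "t", toupper(sequence))
  seq <- chartr("U", "T", seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence for gene '", gene_id, "'")
  rem <- n %% 3L
  if (rem != 0L) {
    warning("gene '", gene_id, "': length ", n,
            " is not a multiple of 3; trimming ", rem, " trailing nt")
    seq_codons <- substr(seq, 1L, n - rem)
  } else {
    seq_codons <- seq
  }
  codons <- substring(seq_codons, seq(1L, nchar(seq_codons), 3L),
                      seq(3L, nchar(seq_codons), 3L))
  clean <- grepl("^[ACGT]{3}$", codons)
  structure(list(
    gene_id = gene_id,
    sequence = seq,
    codons = codons[clean],
    length_nt = 3L * sum(clean),
    ambiguous_codons_dropped = sum(!clean),
    length_ok = rem == 0L
  ), class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat("<gene_record> ", x$gene_id, ": ", x$length_nt, " nt, ",
      length(x$codons), " codons",
      if (x$ambiguous_codons_dropped > 0)
        paste0(" (", x$ambiguous_codons_dropped, " ambiguous dropped)"),
      "\n", sep = "")
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' One `gene_record` per FASTA entry, in file order. The header token before
#' the first whitespace becomes the gene id. Plain or gzipped files are
#' accepted.
#'
#' @param path path to a (multi-)FASTA file.
#' @return list of [gene_record()] objects, named by gene id.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # BStringSet: tolerate RNA alphabet and ambiguity codes; gene_record()
  # normalises case and maps U to T
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  recs <- lapply(seq_along(set), function(i)
    gene_record(ids[i], as.character(set[[i]])))
  names(recs) <- ids
  recs
}

#' Write gene records to a FASTA file
#'
#' Writes the codon sequence of each record (clean codons only), so that
#' re-reading yields identical codon lists.
#'
#' @param records list of `gene_record` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  seqs <- vapply(records, function(r) paste(r$codons, collapse = ""),
                 character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- vapply(records, `[[`, character(1), "gene_id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate a coding sequence
#'
#' Report-only checks: frame (length a multiple of 3), internal stop codons
#' (TAA/TAG/TGA anywhere before the final codon), the presence of a terminal
#' stop, and the number of ambiguous codons that were dropped at parse time.
#'
#' @param record a `gene_record`.
#' @return list of class `cds_validation` with elements `gene_id`,
#'   `length_ok`, `internal_stop_positions` (1-based codon indices),
#'   `ambiguous_codons_dropped` and `has_terminal_stop`.
#' @export
validate_cds <- function(record) {
  stopifnot(inherits(record, "gene_record"))
  codons <- record$codons
  n <- length(codons)
  is_stop <- codons %in% .STOP_CODONS
  internal <- which(is_stop[-n])
  structure(list(
    gene_id = record$gene_id,
    length_ok = isTRUE(record$length_ok),
    internal_stop_positions = as.integer(internal),
    ambiguous_codons_dropped = record$ambiguous_codons_dropped,
    has_terminal_stop = n > 0 && is_stop[n]
  ), class = "cds_validation")
}

#' @export
print.cds_validation <- function(x, ...) {
  cat("<cds_validation> ", x$gene_id,
      ": frame ", if (x$length_ok) "ok" else "TRIMMED",
      ", internal stops: ", length(x$internal_stop_positions),
      ", terminal stop: ", x$has_terminal_stop, "\n", sep = "")
  invisible(x)
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code. The terminal stop codon is excluded from
#' the protein. An internal stop truncates translation with a warning, or is
#' an error under `strict = TRUE`.
#'
#' @param record a `gene_record`.
#' @param strict error (rather than warn and truncate) on internal stops.
#' @return single protein string in one-letter code.
#' @export
translate_cds <- function(record, strict = FALSE) {
  stopifnot(inherits(record, "gene_record"))
  codons <- record$codons
  if (length(codons) == 0L) stop("gene '", record$gene_id, "': no codons")
  aa <- codon_aa(codons)
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0) {
    if (strict)
      stop("gene '", record$gene_id, "': internal stop at codon ", stop_at[1])
    warning("gene '", record$gene_id, "': internal stop at codon ",
            stop_at[1], "; truncating")
    aa <- aa[seq_len(stop_at[1] - 1L)]
  }
  paste(aa, collapse = "")
}
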
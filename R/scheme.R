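#' Subpool barcoding scheme
#'
#' A scheme describes how barcoded amplicon reads map back to wells of an
#' arrayed clone library plate: 24 column barcodes carried on the forward
#' primer and 16 row barcodes carried on the reverse primer address the
#' 24 x 16 = 384 subpools of one PCR plate. The scheme also records how many
#' leading bases (spacer + degenerate primer) to strip from the forward read
#' and the fixed length to which reads are truncated before clustering.
#'
#' @param plate_id Plate label, used as the first component of subpool ids.
#' @param column_barcodes Character vector of 24 distinct DNA barcodes
#'   (8 or 12 nt each), in column order (columns 1..24).
#' @param row_barcodes Character vector of 16 distinct DNA barcodes, in row
#'   order (rows 1..16).
#' @param primer_len Number of bases (spacer + degenerate primer) removed from
#'   the start of each forward read after the column barcode has been stripped.
#' @param total_len Fixed length (nt) to which barcode-stripped forward reads
#'   are truncated before primer removal; shorter reads are discarded.
#' @param spacer Spacer length in nt (recorded for provenance; spacer bases
#'   are consumed by \code{primer_len} during trimming).
#' @param domain_type Label of the amplified domain (e.g. \code{"AD"},
#'   \code{"KS"}).
#'
#' @return An object of class \code{"subpool_scheme"}.
#' @export
subpool_scheme <- function(plate_id, column_barcodes, row_barcodes,
                           primer_len, total_len, spacer = 0L,
                           domain_type = "AD") {
  column_barcodes <- toupper(as.character(column_barcodes))
  row_barcodes <- toupper(as.character(row_barcodes))
  if (length(column_barcodes) != 24L)
    stop("scheme error: expected 24 column barcodes, got ",
         length(column_barcodes))
  if (length(row_barcodes) != 16L)
    stop("scheme error: expected 16 row barcodes, got ", length(row_barcodes))
  if (anyDuplicated(column_barcodes))
    stop("scheme error: duplicate column barcode")
  if (anyDuplicated(row_barcodes))
    stop("scheme error: duplicate row barcode")
  all_bc <- c(column_barcodes, row_barcodes)
  if (!all(nchar(all_bc) %in% c(8L, 12L)))
    stop("scheme error: barcodes must be 8 or 12 nt")
  if (!all(grepl("^[ACGT]+$", all_bc)))
    stop("scheme error: barcodes must be A/C/G/T only")
  primer_len <- as.integer(primer_len)
  total_len <- as.integer(total_len)
  if (primer_len >= total_len)
    stop("scheme error: primer_len must be < total_len")
  structure(
    list(plate_id = as.character(plate_id),
         column_barcodes = column_barcodes,
         row_barcodes = row_barcodes,
         primer_len = primer_len,
         total_len = total_len,
         spacer = as.integer(spacer),
         domain_type = as.character(domain_type)),
    class = "subpool_scheme")
}

#' @export
print.subpool_scheme <- function(x, ...) {
  cat(sprintf(
    "subpool_scheme: plate %s, %d x %d = %d subpools, domain %s\n",
    x$plate_id, length(x$row_barcodes), length(x$column_barcodes),
    length(x$row_barcodes) * length(x$column_barcodes), x$domain_type))
  cat(sprintf("  primer_len %d nt, total_len %d nt (trimmed reads %d nt)\n",
              x$primer_len, x$total_len, x$total_len - x$primer_len))
  invisible(x)
}

#' All subpool identifiers addressable under a scheme
#'
#' Identifiers have the form \code{<plate>_r<row>_c<column>}, rows 1..16 and
#' columns 1..24, ordered row-major.
#'
#' @param scheme A \code{subpool_scheme}.
#' @return Character vector of 384 subpool ids.
#' @export
subpool_ids <- function(scheme) {
  stopifnot(inherits(scheme, "subpool_scheme"))
  grid <- expand.grid(col = seq_along(scheme$column_barcodes),
                      row = seq_along(scheme$row_barcodes))
  sprintf("%s_r%d_c%d", scheme$plate_id, grid$row, grid$col)
}

#' Read a subpool scheme from a TSV file
#'
#' The file holds header key/value lines of the form \code{#key<TAB>value}
#' for \code{plate_id}, \code{primer_len}, \code{total_len}, \code{spacer}
#' and \code{domain_type}, followed by a three-column table with header
#' \code{barcode}, \code{axis} (\code{row} or \code{column}) and \code{index}
#' (1-based position along the axis). The same barcode may appear under both
#' axes: the two barcode sets are matched independently against the forward
#' and reverse read.
#'
#' @param path Path to the scheme TSV.
#' @return A validated \code{subpool_scheme}.
#' @export
parse_scheme <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  need <- c("primer_len", "total_len")
  if (!all(need %in% keys))
    stop("scheme error: missing header keys: ",
         paste(setdiff(need, keys), collapse = ", "))
  get <- function(k, default = NA_character_)
    if (k %in% keys) vals[match(k, keys)] else default
  tab <- utils::read.delim(textConnection(grep("^#", lines, value = TRUE,
                                               invert = TRUE)),
                           stringsAsFactors = FALSE)
  if (!all(c("barcode", "axis", "index") %in% names(tab)))
    stop("scheme error: table must have columns barcode, axis, index")
  cols <- tab[tab$axis == "column", ]
  rows <- tab[tab$axis == "row", ]
  if (nrow(cols) != 24L)
    stop("scheme error: expected 24 column barcodes, got ", nrow(cols))
  if (nrow(rows) != 16L)
    stop("scheme error: expected 16 row barcodes, got ", nrow(rows))
  subpool_scheme(
    plate_id = get("plate_id", "P1"),
    column_barcodes = cols$barcode[order(cols$index)],
    row_barcodes = rows$barcode[order(rows$index)],
    primer_len = as.integer(get("primer_len")),
    total_len = as.integer(get("total_len")),
    spacer = as.integer(get("spacer", "0")),
    domain_type = get("domain_type", "AD"))
}

#' Write a subpool scheme to a TSV file
#'
#' Inverse of [parse_scheme()].
#'
#' @param scheme A \code{subpool_scheme}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "subpool_scheme"))
  hdr <- c(paste0("#plate_id\t", scheme$plate_id),
           paste0("#primer_len\t", scheme$primer_len),
           paste0("#total_len\t", scheme$total_len),
           paste0("#spacer\t", scheme$spacer),
           paste0("#domain_type\t", scheme$domain_type))
  tab <- rbind(
    data.frame(barcode = scheme$column_barcodes, axis = "column",
               index = seq_along(scheme$column_barcodes)),
    data.frame(barcode = scheme$row_barcodes, axis = "row",
               index = seq_along(scheme$row_barcodes)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Hamming distances between the length-n prefix of each read and one barcode.
## Reads whose prefix contains N are pushed beyond any mismatch budget.
.prefix_dist <- function(prefixes, barcode) {
  n <- nchar(barcode)
  d <- integer(length(prefixes))
  for (j in seq_len(n)) {
    d <- d + (substr(prefixes, j, j) != substr(barcode, j, j))
  }
  too_short <- nchar(prefixes) < n
  has_n <- grepl("N", substr(prefixes, 1L, n), fixed = TRUE)
  d[too_short | has_n] <- n + 1L
  d
}

## Match read prefixes against one barcode set. Returns the 1-based barcode
## index, or 0 (no match within budget) or -1 (ambiguous best match).
.match_axis <- function(seqs, barcodes, max_mismatch) {
  maxlen <- max(nchar(barcodes))
  prefixes <- substr(seqs, 1L, maxlen)
  D <- vapply(barcodes, function(b) .prefix_dist(prefixes, b),
              integer(length(seqs)))
  D <- matrix(D, nrow = length(seqs))
  best <- apply(D, 1L, min)
  hit <- integer(length(seqs))
  ok <- best <= max_mismatch
  n_best <- rowSums(D == best)
  hit[ok & n_best == 1L] <- apply(D[ok & n_best == 1L, , drop = FALSE],
                                  1L, which.min)
  hit[ok & n_best > 1L] <- -1L
  hit
}

#' Assign a read pair to a library subpool
#'
#' The forward read's prefix is matched against the column barcodes and the
#' reverse read's prefix against the row barcodes, each within
#' \code{max_mismatch} Hamming distance; a unique best match on both axes is
#' required. Reads with an \code{N} inside the barcode window are never
#' assigned on that axis. Unassignable pairs are data, not errors: they are
#' returned with a categorical reason.
#'
#' @param fwd_seq,rev_seq Forward (R1) and reverse (R2) read sequences.
#' @param scheme A \code{subpool_scheme}.
#' @param max_mismatch Maximum Hamming distance allowed when matching a
#'   barcode (default 0, i.e. exact matching).
#' @return A list with \code{subpool_id} (or \code{NA}), \code{row},
#'   \code{col} and \code{reason} (\code{"assigned"}, \code{"no_column"},
#'   \code{"no_row"} or \code{"ambiguous"}).
#' @export
assign_subpool <- function(fwd_seq, rev_seq, scheme, max_mismatch = 0L) {
  res <- assign_subpools(fwd_seq, rev_seq, scheme, max_mismatch)
  list(subpool_id = res$subpool_id[1L], row = res$row[1L], col = res$col[1L],
       reason = res$reason[1L])
}

#' Vectorised subpool assignment
#'
#' @inheritParams assign_subpool
#' @return A data.frame with one row per read pair: \code{subpool_id},
#'   \code{row}, \code{col}, \code{reason}.
#' @export
assign_subpools <- function(fwd_seq, rev_seq, scheme, max_mismatch = 0L) {
  stopifnot(inherits(scheme, "subpool_scheme"),
            length(fwd_seq) == length(rev_seq), max_mismatch >= 0L)
  fwd_seq <- toupper(as.character(fwd_seq))
  rev_seq <- toupper(as.character(rev_seq))
  col_hit <- .match_axis(fwd_seq, scheme$column_barcodes, max_mismatch)
  row_hit <- .match_axis(rev_seq, scheme$row_barcodes, max_mismatch)
  reason <- rep("assigned", length(fwd_seq))
  reason[col_hit == 0L] <- "no_column"
  reason[col_hit != 0L & row_hit == 0L] <- "no_row"
  reason[col_hit == -1L | (col_hit > 0L & row_hit == -1L)] <- "ambiguous"
  ok <- reason == "assigned"
  subpool_id <- rep(NA_character_, length(fwd_seq))
  subpool_id[ok] <- sprintf("%s_r%d_c%d", scheme$plate_id,
                            row_hit[ok], col_hit[ok])
  data.frame(subpool_id = subpool_id,
             row = ifelse(ok, row_hit, NA_integer_),
             col = ifelse(ok, col_hit, NA_integer_),
             reason = reason, stringsAsFactors = FALSE)
}

#' Trim a barcode-stripped forward read to a fixed-length domain sequence
#'
#' Reads are truncated to \code{total_len} nt and the first \code{primer_len}
#' nt (spacer + degenerate primer) are removed, yielding sequences of exactly
#' \code{total_len - primer_len} nt. Reads shorter than \code{total_len} are
#' discarded (\code{NA}).
#'
#' @param seq Character vector of DNA sequences (barcode already removed).
#' @param primer_len,total_len Trimming parameters; \code{primer_len} must be
#'   smaller than \code{total_len}.
#' @return Character vector of trimmed sequences, \code{NA} where discarded.
#' @export
trim_read <- function(seq, primer_len, total_len) {
  stopifnot(primer_len < total_len)
  out <- substr(seq, primer_len + 1L, total_len)
  out[nchar(seq) < total_len] <- NA_character_
  out
}

#' Demultiplex paired FASTQ files into per-subpool trimmed read sets
#'
#' Reads are assigned to subpools by their column/row barcodes, the column
#' barcode is stripped from the forward read, and the remainder is trimmed to
#' a fixed-length, primer-free domain sequence. Only the forward read is
#' carried forward; the reverse read serves solely for row-barcode
#' assignment. Per-subpool FASTA files and a demultiplexing report are
#' written when \code{out_dir} is given.
#'
#' @param r1,r2 Paths to the forward and reverse FASTQ files (optionally
#'   gzipped).
#' @param scheme A \code{subpool_scheme}.
#' @param max_mismatch Barcode mismatch budget (default 0).
#' @param out_dir Output directory for per-subpool FASTA files named
#'   \code{<subpool_id>.fasta} and \code{demux_report.tsv}; \code{NULL} to
#'   skip writing.
#' @return Invisibly, a list with \code{reads} (data.frame of
#'   \code{subpool_id}, trimmed \code{seq}) and \code{report} (counts per
#'   assignment category).
#' @export
demux_fastq <- function(r1, r2, scheme, max_mismatch = 0L, out_dir = NULL) {
  fwd <- Biostrings::readDNAStringSet(r1, format = "fastq")
  rev <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(fwd) != length(rev))
    stop("R1 and R2 have different read counts")
  res <- demux_pairs(as.character(fwd), as.character(rev), scheme,
                     max_mismatch)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    by_pool <- split(res$reads$seq, res$reads$subpool_id)
    for (sp in names(by_pool)) {
      ss <- Biostrings::DNAStringSet(by_pool[[sp]])
      names(ss) <- sprintf("%s_read%d", sp, seq_along(ss))
      Biostrings::writeXStringSet(ss, file.path(out_dir,
                                                paste0(sp, ".fasta")))
    }
    utils::write.table(res$report,
                       file.path(out_dir, "demux_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}

#' Demultiplex in-memory read pairs
#'
#' Core of [demux_fastq()]: assigns each pair to a subpool, strips the
#' column barcode from the forward read and applies fixed-length trimming.
#'
#' @param fwd_seq,rev_seq Character vectors of read sequences.
#' @inheritParams demux_fastq
#' @return A list with \code{reads} (data.frame \code{subpool_id},
#'   \code{seq}) and \code{report} (data.frame \code{subpool_id},
#'   \code{category}, \code{n}; unassigned categories use subpool_id
#'   \code{NA}).
#' @export
demux_pairs <- function(fwd_seq, rev_seq, scheme, max_mismatch = 0L) {
  asn <- assign_subpools(fwd_seq, rev_seq, scheme, max_mismatch)
  ok <- asn$reason == "assigned"
  # strip the matched column barcode, then trim to fixed length
  bc_len <- nchar(scheme$column_barcodes)[asn$col[ok]]
  stripped <- substr(fwd_seq[ok], bc_len + 1L, nchar(fwd_seq[ok]))
  trimmed <- trim_read(stripped, scheme$primer_len, scheme$total_len)
  keep <- !is.na(trimmed)
  reads <- data.frame(subpool_id = asn$subpool_id[ok][keep],
                      seq = trimmed[keep], stringsAsFactors = FALSE)
  # report categories partition the input reads
  n_short <- sum(!keep)
  cat_counts <- table(asn$reason)
  cats <- names(cat_counts)
  n_cat <- as.integer(cat_counts)
  n_cat[cats == "assigned"] <- n_cat[cats == "assigned"] - n_short
  report <- data.frame(
    category = c(cats, "assigned_too_short"),
    n = c(n_cat, n_short),
    stringsAsFactors = FALSE)
  list(reads = reads, report = report)
}
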
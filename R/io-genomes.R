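#' Read genome annotation (GFF3 CDS features + protein FASTA) into a CDS table
#'
#' Parses CDS features from a GFF3 file (via rtracklayer) and, optionally,
#' joins translated protein sequences from a FASTA file by protein id. The
#' result is one row per CDS, ranked in genomic order within each contig:
#' `index` is the 0-based rank of the CDS start coordinate on its contig,
#' regardless of the order of rows in the file and regardless of strand.
#'
#' Proteins present in the FASTA but absent from the GFF3 are kept as orphan
#' rows (`contig_id` and coordinates `NA`): they remain usable for sequence
#' clustering and identity statistics but are excluded from neighbourhood
#' analysis. CDS features without a `protein_id` attribute are skipped with
#' a warning stating how many were dropped. A duplicated protein id among
#' CDS features is an error.
#'
#' @param gff_path Path to a GFF3 file with CDS features carrying a
#'   `protein_id` (or `ID`) attribute and `##sequence-region` pragmas.
#' @param fasta_path Optional path to a protein FASTA of translations.
#' @param assembly_id Assembly identifier recorded on every row; defaults to
#'   the GFF3 file name without extension.
#' @return A tibble with columns `assembly_id`, `contig_id`,
#'   `contig_length`, `protein_id`, `index`, `start`, `end`, `strand`,
#'   `aa_seq` (NA when no FASTA given).
#' @seealso [contig_table()] for contigs (including CDS-less ones),
#'   [write_gff3()] for the inverse operation.
#' @export
read_genome_annotation <- function(gff_path, fasta_path = NULL,
                                   assembly_id = NULL) {
  assembly_id <- assembly_id %||%
    sub("\\.(gff3?|gff)$", "", basename(gff_path))
  contigs <- contig_table(gff_path)

  gr <- rtracklayer::import(gff_path, format = "gff3")
  feat <- as.data.frame(gr, stringsAsFactors = FALSE)
  feat <- feat[as.character(feat$type) == "CDS", , drop = FALSE]
  pid <- if ("protein_id" %in% names(feat)) {
    as.character(feat$protein_id)
  } else if ("ID" %in% names(feat)) {
    as.character(feat$ID)
  } else {
    rep(NA_character_, nrow(feat))
  }

  n_skipped <- sum(is.na(pid) | pid == "")
  if (n_skipped > 0) {
    rlang::warn(sprintf("skipped %d CDS feature(s) without a protein id",
                        n_skipped))
  }
  keep <- !(is.na(pid) | pid == "")
  feat <- feat[keep, , drop = FALSE]
  pid <- pid[keep]
  if (anyDuplicated(pid)) {
    rlang::abort(sprintf("duplicate protein id(s) in %s: %s", gff_path,
                         paste(unique(pid[duplicated(pid)]), collapse = ", ")))
  }

  cds <- tibble::tibble(
    assembly_id = assembly_id,
    contig_id   = as.character(feat$seqnames),
    protein_id  = pid,
    start       = as.integer(feat$start),
    end         = as.integer(feat$end),
    strand      = as.character(feat$strand)
  ) |>
    dplyr::mutate(strand = ifelse(.data$strand == "*", "+", .data$strand)) |>
    dplyr::arrange(.data$contig_id, .data$start, .data$end) |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::mutate(index = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::left_join(contigs, by = "contig_id") |>
    dplyr::rename(contig_length = "length_bp") |>
    dplyr::select("assembly_id", "contig_id", "contig_length", "protein_id",
                  "index", "start", "end", "strand")

  if (!is.null(fasta_path)) {
    seqs <- read_protein_fasta(fasta_path)
    cds <- dplyr::left_join(cds, seqs, by = "protein_id")
    orphans <- dplyr::anti_join(seqs, cds, by = "protein_id")
    if (nrow(orphans) > 0) {
      cds <- dplyr::bind_rows(
        cds,
        dplyr::mutate(orphans, assembly_id = assembly_id)
      )
    }
  } else {
    cds$aa_seq <- NA_character_
  }
  cds
}

#' Contig table from GFF3 sequence-region pragmas
#'
#' Contigs are taken from `##sequence-region` pragma lines, so contigs
#' without any CDS are still reported (with `n_cds = 0`).
#'
#' @param gff_path Path to a GFF3 file.
#' @return Tibble with `contig_id`, `length_bp`, `n_cds`.
#' @export
contig_table <- function(gff_path) {
  lines <- readr::read_lines(gff_path)
  prag <- grep("^##sequence-region", lines, value = TRUE)
  fields <- strsplit(trimws(prag), "\\s+")
  contigs <- tibble::tibble(
    contig_id = vapply(fields, function(f) f[2], character(1)),
    length_bp = vapply(fields, function(f) as.integer(f[4]), integer(1))
  )
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  seqn <- vapply(strsplit(body, "\t"), function(f) f[1], character(1))
  types <- vapply(strsplit(body, "\t"),
                  function(f) if (length(f) >= 3) f[3] else NA_character_,
                  character(1))
  cds_counts <- table(seqn[types %in% "CDS"])
  contigs$n_cds <- as.integer(cds_counts[contigs$contig_id])
  contigs$n_cds[is.na(contigs$n_cds)] <- 0L
  contigs
}

#' Write a CDS table back to GFF3
#'
#' Inverse of [read_genome_annotation()]: emits one CDS feature per row
#' (orphan rows without coordinates are dropped) plus `##sequence-region`
#' pragmas so contig lengths round-trip.
#'
#' @param cds CDS tibble as produced by [read_genome_annotation()].
#' @param path Output file path.
#' @param contig_lengths Optional named vector of contig lengths overriding
#'   the `contig_length` column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(cds, path, contig_lengths = NULL) {
  check_columns(cds, c("contig_id", "protein_id", "start", "end", "strand"),
                "`cds`")
  placed <- dplyr::filter(cds, !is.na(.data$contig_id), !is.na(.data$start))
  if (is.null(contig_lengths)) {
    ct <- dplyr::distinct(placed, .data$contig_id, .data$contig_length)
    contig_lengths <- setNames(ct$contig_length, ct$contig_id)
  }
  placed <- dplyr::arrange(placed, .data$contig_id, .data$start, .data$end)
  seqinfo <- GenomeInfoDb::Seqinfo(
    seqnames = names(contig_lengths),
    seqlengths = as.integer(contig_lengths)
  )
  gr <- GenomicRanges::GRanges(
    seqnames = placed$contig_id,
    ranges = IRanges::IRanges(start = placed$start, end = placed$end),
    strand = placed$strand,
    seqinfo = seqinfo
  )
  gr$type <- "CDS"
  gr$source <- "anchorscan"
  gr$phase <- 0L
  gr$ID <- placed$protein_id
  gr$protein_id <- placed$protein_id
  rtracklayer::export(gr, path, format = "gff3")
  # make sure sequence-region pragmas are present (needed to round-trip
  # contig lengths, and to keep CDS-less contigs)
  lines <- readr::read_lines(path)
  have <- grepl("^##sequence-region", lines)
  want <- sprintf("##sequence-region %s 1 %d", names(contig_lengths),
                  as.integer(contig_lengths))
  missing <- !vapply(names(contig_lengths), function(cid) {
    any(grepl(paste0("^##sequence-region\\s+", cid, "\\s"), lines))
  }, logical(1))
  if (any(missing)) {
    lines <- append(lines, want[missing], after = 1L)
    readr::write_lines(lines, path)
  }
  invisible(path)
}

#' Read a protein FASTA into a tibble
#'
#' @param path FASTA file of amino-acid sequences; the protein id is the
#'   first whitespace-delimited word of each header.
#' @return Tibble with `protein_id`, `aa_seq`.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    protein_id = vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1),
    aa_seq = unname(as.character(ss))
  )
}

#' Write protein sequences to FASTA
#'
#' @param seqs Tibble with `protein_id`, `aa_seq` (rows without a sequence
#'   are dropped).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  check_columns(seqs, c("protein_id", "aa_seq"), "`seqs`")
  seqs <- dplyr::filter(seqs, !is.na(.data$aa_seq))
  ss <- Biostrings::AAStringSet(setNames(seqs$aa_seq, seqs$protein_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an assembly taxonomy/QC table
#'
#' @param path TSV with columns `assembly_id`, `class_label`,
#'   `completeness`, `contamination`.
#' @return Tibble with those columns.
#' @export
read_taxonomy_qc <- function(path) {
  qc <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(qc, c("assembly_id", "class_label", "completeness",
                      "contamination"), path)
  qc
}
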
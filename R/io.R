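#' Read mature miRNA sequences from FASTA
#'
#' Reads a miRBase-style mature FASTA file. The header token before the first
#' whitespace becomes the id (the remainder is kept as `description`),
#' `T`/`t` are normalised to `U`, and lowercase letters are uppercased, so
#' DNA-style records are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with `mirna_id`, `sequence` (strictly over `A`,`C`,`G`,`U`)
#'   and `description`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-miR-148a-3p MIMAT0000243", "UCAGUGCACUACAGAACUUUGU"), tf)
#' read_mature_fasta(tf)
read_mature_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "mirexport_format_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    abort(sprintf("not a readable FASTA file: %s",
                                  conditionMessage(e)),
                          class = "mirexport_format_error")
                  })
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- trimws(sub("^\\S+\\s*", "", headers))
  seqs <- unname(as.character(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]),
          class = "mirexport_format_error")
  }
  seqs <- chartr("Tt", "Uu", seqs)
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    abort(sprintf("non-IUPAC RNA character in record '%s'", ids[bad][1]),
          class = "mirexport_format_error")
  }
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence in record '%s'", ids[!nzchar(seqs)][1]),
          class = "mirexport_format_error")
  }
  tibble(mirna_id = unname(ids), sequence = unname(seqs),
         description = unname(descriptions))
}

#' Write sequences as FASTA
#'
#' @param sequences Tibble with `mirna_id` and `sequence` (optionally
#'   `description`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mature_fasta <- function(sequences, path) {
  desc <- sequences[["description"]] %||% rep("", nrow(sequences))
  header <- ifelse(nzchar(desc),
                   paste0(">", sequences$mirna_id, " ", desc),
                   paste0(">", sequences$mirna_id))
  writeLines(as.vector(rbind(header, sequences$sequence)), path)
  invisible(path)
}

#' Read a miRNA count table with sample metadata
#'
#' The count table is tab-separated with the miRNA id in the first column and
#' sample ids in the header; the metadata table maps each `sample_id` to
#' `compartment` (`cell`/`EV`), `condition` (`CONT`/`CAVIN1`) and
#' `replicate`.
#'
#' @param path Path to the tab-separated count table.
#' @param meta_path Path to the tab-separated sample metadata table.
#' @return A list with `counts` (tibble) and `samples` (tibble), validated:
#'   counts integral and non-negative, metadata covering every sample, no
#'   duplicate ids.
#' @export
read_count_table <- function(path, meta_path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(counts)[1] <- "mirna_id"
  samples <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  validate_count_matrix(counts, samples)
  list(counts = counts, samples = samples)
}

validate_count_matrix <- function(counts, samples) {
  if (anyDuplicated(counts$mirna_id)) {
    abort("duplicate miRNA ids in count table", class = "mirexport_format_error")
  }
  sample_cols <- setdiff(names(counts), "mirna_id")
  if (anyDuplicated(sample_cols)) {
    abort("duplicate sample ids in count table", class = "mirexport_format_error")
  }
  for (col in sample_cols) {
    v <- counts[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf("non-integer or negative count at miRNA '%s', sample '%s'",
                    counts$mirna_id[bad[1]], col),
            class = "mirexport_format_error")
    }
  }
  missing <- setdiff(sample_cols, samples$sample_id)
  if (length(missing)) {
    abort(sprintf("sample '%s' has no metadata", missing[1]),
          class = "mirexport_format_error")
  }
  bad_comp <- setdiff(unique(samples$compartment), c("cell", "EV"))
  if (length(bad_comp)) {
    abort(sprintf("unknown compartment '%s'", bad_comp[1]),
          class = "mirexport_format_error")
  }
  invisible(TRUE)
}

#' Write a count table and its sample metadata
#'
#' @param counts,samples Tibbles as returned by
#'   [simulate_count_experiment()].
#' @param path,meta_path Output paths (tab-separated).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, samples, path, meta_path) {
  readr::write_tsv(counts, path, progress = FALSE)
  readr::write_tsv(samples, meta_path, progress = FALSE)
  invisible(path)
}

#' Read a protein intensity table with group labels
#'
#' @param path Tab-separated intensity table, protein id in the first column.
#' @param groups_path Tab-separated table with `sample_id` and `group`
#'   (`early`/`metastatic`).
#' @return A list with `intensities` and `groups` tibbles; intensities must
#'   be strictly positive and every group sample present in the table.
#' @export
read_intensity_table <- function(path, groups_path) {
  intensities <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(intensities)[1] <- "protein_id"
  groups <- readr::read_tsv(groups_path, show_col_types = FALSE, progress = FALSE)
  sample_cols <- setdiff(names(intensities), "protein_id")
  for (col in sample_cols) {
    v <- intensities[[col]]
    if (any(!is.finite(v) | v <= 0)) {
      abort(sprintf("non-positive intensity in sample '%s'", col),
            class = "mirexport_format_error")
    }
  }
  missing <- setdiff(groups$sample_id, sample_cols)
  if (length(missing)) {
    abort(sprintf("group file names sample '%s' absent from the table", missing[1]),
          class = "mirexport_format_error")
  }
  if (length(unique(groups$group)) < 2L) {
    abort("both groups must be non-empty", class = "mirexport_format_error")
  }
  list(intensities = intensities, groups = groups)
}

#' Write a result table
#'
#' Tab-separated, one row per record, with a header, deterministic column
#' order (as given) and full-precision reals.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}
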
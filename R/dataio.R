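#' Construct a circRNA-disease association dataset
#'
#' Builds the binary association matrix `A` (circRNAs in rows, diseases in
#' columns) from a table of known association pairs. Row and column order is
#' lexicographic over the identifiers so matrices are reproducible across runs;
#' duplicate pairs are counted once. Entity identity is exact string match
#' after trimming surrounding whitespace.
#'
#' @param pairs data frame with columns `circ_id` and `disease_id`, one row per
#'   known association.
#' @return An object of class `circ_dataset`: a list with the 0/1 matrix `A`
#'   (dimnames carry the identifiers), plus `circ_ids` and `disease_ids`.
#' @examples
#' d <- circ_dataset(data.frame(circ_id = c("c1", "c1", "c2"),
#'                              disease_id = c("d1", "d2", "d1")))
#' d$A
#' @export
circ_dataset <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("circ_id", "disease_id") %in% names(pairs))) {
    abort("`pairs` must have columns `circ_id` and `disease_id`.")
  }
  if (nrow(pairs) == 0) abort("no association pairs supplied.")
  ci <- trimws(as.character(pairs$circ_id))
  di <- trimws(as.character(pairs$disease_id))
  bad <- which(ci == "" | di == "" | is.na(ci) | is.na(di))
  if (length(bad) > 0) {
    abort(paste0("malformed association row(s): ", paste(bad, collapse = ", ")))
  }
  circ_ids <- sort(unique(ci))
  disease_ids <- sort(unique(di))
  A <- matrix(0L, length(circ_ids), length(disease_ids),
              dimnames = list(circ_ids, disease_ids))
  A[cbind(match(ci, circ_ids), match(di, disease_ids))] <- 1L
  new_circ_dataset(A)
}

new_circ_dataset <- function(A) {
  storage.mode(A) <- "integer"
  structure(list(A = A, circ_ids = rownames(A), disease_ids = colnames(A)),
            class = "circ_dataset")
}

#' @export
print.circ_dataset <- function(x, ...) {
  cat(sprintf("<circ_dataset> %d circRNAs x %d diseases, %d known associations (density %.4f)\n",
              nrow(x$A), ncol(x$A), sum(x$A), matrix_density(x)))
  invisible(x)
}

#' @describeIn circ_dataset number of known associations `|Omega|`.
#' @param x,object a `circ_dataset`.
#' @export
n_associations <- function(x) sum(x$A)

#' @describeIn circ_dataset known pairs as a tibble (`circ_id`, `disease_id`).
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.circ_dataset <- function(x, ...) {
  idx <- which(x$A == 1L, arr.ind = TRUE)
  tibble(circ_id = x$circ_ids[idx[, 1]],
         disease_id = x$disease_ids[idx[, 2]]) |>
    dplyr::arrange(.data$circ_id, .data$disease_id)
}

#' @describeIn circ_dataset one-row summary (dimensions, associations, density).
#' @exportS3Method generics::glance
glance.circ_dataset <- function(x, ...) {
  tibble(n_circ = nrow(x$A), n_disease = ncol(x$A),
         n_associations = sum(x$A), density = matrix_density(x))
}

#' Read a circRNA-disease association table
#'
#' Reads a delimited file with header columns `circ_id` and `disease_id` and
#' assembles the association matrix. Pairs are deduplicated; entity order is
#' lexicographic.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field delimiter; `"\t"` (default) or `","`.
#' @return A [circ_dataset()].
#' @export
read_associations <- function(path, sep = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, colClasses = "character",
               check.names = FALSE, strip.white = TRUE),
    error = function(e) abort(paste0("parse error in ", path, ": ", conditionMessage(e))))
  if (nrow(tab) == 0) abort(paste0("empty association file: ", path))
  if (!all(c("circ_id", "disease_id") %in% names(tab))) {
    abort("association table must have header columns `circ_id` and `disease_id`.")
  }
  bad <- which(trimws(tab$circ_id) == "" | trimws(tab$disease_id) == "")
  if (length(bad) > 0) {
    abort(paste0("malformed row at line ", bad[1] + 1L, " of ", path))
  }
  circ_dataset(tab)
}

#' Write an association dataset as TSV
#'
#' @param dataset a [circ_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(dataset, path) {
  write.table(as.data.frame(tidy(dataset)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read circRNA sequences from FASTA
#'
#' Sequences are uppercased and `U` is mapped to `T` so that downstream edit
#' distances are computed over a single DNA alphabet regardless of whether the
#' source used RNA or DNA letters.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences over `{A,C,G,T}`, names are the
#'   record identifiers (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]))
  }
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) abort(paste0("empty sequence for record ", ids[empty[1]]))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    abort(paste0("non-ACGT/U residue in record ", ids[which(bad)[1]]))
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Drop associations with incomplete side information
#'
#' Keeps only associations whose circRNA has a sequence and whose disease is a
#' (non-obsolete) term of the ontology; rows and columns left without any
#' association are dropped. Mirrors the dataset-assembly step that excludes
#' "uncompleted" associations lacking a sequence or a DOID.
#'
#' @param dataset a [circ_dataset()].
#' @param sequences named character vector as returned by [read_fasta()].
#' @param ontology an [onto_dag] as returned by [read_obo()].
#' @return A filtered [circ_dataset()].
#' @export
filter_complete <- function(dataset, sequences, ontology) {
  pairs <- tidy(dataset)
  keep <- pairs$circ_id %in% names(sequences) &
    pairs$disease_id %in% ontology$terms
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) abort("filtering removed every association.")
  circ_dataset(pairs)
}

#' Merge association datasets
#'
#' Union of the entity sets and of the association pairs across datasets, with
#' exact string identity and each pair counted once (no duplicated redundancy).
#'
#' @param datasets list of [circ_dataset()] objects.
#' @return The merged [circ_dataset()].
#' @export
merge_datasets <- function(datasets) {
  if (length(datasets) == 0) abort("need at least one dataset to merge.")
  circ_dataset(dplyr::bind_rows(lapply(datasets, tidy)))
}

#' Density of the association matrix
#'
#' @param dataset a [circ_dataset()].
#' @return `|Omega| / (m * n)`, the fraction of known entries.
#' @export
matrix_density <- function(dataset) {
  sum(dataset$A) / length(dataset$A)
}

#' Randomly sparsify a dataset to a target density
#'
#' Removes uniformly random known associations (matrix dimensions held fixed)
#' until the density is at most `target_density`. Used to probe how prediction
#' degrades as the association matrix gets sparser. At least one association is
#' always kept.
#'
#' @param dataset a [circ_dataset()].
#' @param target_density target fraction of known entries, in (0, current density].
#' @param seed integer seed for the random removal.
#' @return A [circ_dataset()] with the same dimensions and fewer associations.
#' @export
sparsify <- function(dataset, target_density, seed = 1L) {
  if (target_density <= 0) abort("`target_density` must be positive.")
  cur <- matrix_density(dataset)
  if (target_density > cur) {
    abort(sprintf("`target_density` (%.4f) exceeds current density (%.4f).",
                  target_density, cur))
  }
  A <- dataset$A
  n_keep <- max(1L, floor(target_density * length(A)))
  ones <- which(A == 1L)
  n_drop <- length(ones) - n_keep
  if (n_drop > 0) {
    set.seed(seed)
    A[sample(ones, n_drop)] <- 0L
  }
  new_circ_dataset(A)
}
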
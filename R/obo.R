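#' Disease ontology DAG
#'
#' A minimal ontology container: term identifiers plus the `is_a` parent map.
#' Edges run child -> parent and the graph must be acyclic (a DAG; multiple
#' parents are allowed, as in the Disease Ontology).
#'
#' @param terms character vector of term ids.
#' @param parents named list mapping each term to a character vector of its
#'   `is_a` parents (possibly empty).
#' @return An object of class `onto_dag`.
#' @export
onto_dag <- function(terms, parents) {
  terms <- unique(as.character(terms))
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) {
    p <- unique(as.character(p))
    p[!is.na(p)]
  })
  extra <- setdiff(unique(unlist(parents)), terms)
  if (length(extra) > 0) {
    terms <- c(terms, extra)
    parents <- c(parents, stats::setNames(rep(list(character(0)), length(extra)), extra))
  }
  obj <- structure(list(terms = terms, parents = parents), class = "onto_dag")
  cyc <- find_cycle(obj)
  if (!is.null(cyc)) {
    abort(paste0("ontology contains a cycle: ", paste(cyc, collapse = " -> ")))
  }
  obj
}

#' @export
print.onto_dag <- function(x, ...) {
  cat(sprintf("<onto_dag> %d terms, %d is_a edges\n",
              length(x$terms), sum(lengths(x$parents))))
  invisible(x)
}

# Kahn topological sort over child->parent edges; returns NULL if acyclic,
# otherwise one directed cycle (as a vector of term ids).
find_cycle <- function(onto) {
  terms <- onto$terms
  indeg <- stats::setNames(lengths(onto$parents), terms)
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) for (p in onto$parents[[t]]) {
    children[[p]] <- c(children[[p]], t)
  }
  queue <- terms[indeg == 0]
  seen <- 0L
  while (length(queue) > 0) {
    t <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(terms)) return(NULL)
  # walk parent pointers inside the residual set until a repeat closes a cycle
  residual <- terms[indeg > 0]
  cur <- residual[1]
  path <- character(0)
  while (!(cur %in% path)) {
    path <- c(path, cur)
    cur <- intersect(onto$parents[[cur]], residual)[1]
  }
  c(path[which(path == cur):length(path)], cur)
}

#' Read an ontology from OBO 1.2 format
#'
#' Parses `[Term]` stanzas honoring `id`, `name`, `is_a` and `is_obsolete`
#' fields. Obsolete terms are skipped; `is_a` targets not defined in the file
#' are kept as parentless terms. Errors if the `is_a` graph has a cycle.
#'
#' @param path path to an `.obo` file.
#' @return An [onto_dag()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  terms <- character(0)
  parents <- list()
  cur_id <- NULL
  cur_parents <- character(0)
  obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur_id) && !obsolete) {
      terms <<- c(terms, cur_id)
      parents[[cur_id]] <<- cur_parents
    }
  }
  for (ln in lines) {
    ln <- trimws(sub("!.*$", "", ln))
    if (ln == "[Term]") {
      flush(); in_term <- TRUE
      cur_id <- NULL; cur_parents <- character(0); obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE; cur_id <- NULL
    } else if (in_term && grepl("^id:", ln)) {
      cur_id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
    } else if (in_term && grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- TRUE
    }
  }
  flush()
  if (length(terms) == 0) abort(paste0("no terms found in ", path))
  onto_dag(terms, parents)
}

#' Write an ontology in OBO 1.2 format
#'
#' @param ontology an [onto_dag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ontology$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t), paste0("name: ", t)), con)
    for (p in ontology$parents[[t]]) {
      writeLines(paste0("is_a: ", p), con)
    }
  }
  invisible(path)
}

# All ancestors of `term` (including itself), by upward BFS over is_a edges.
onto_ancestors <- function(onto, term) {
  anc <- character(0)
  queue <- term
  while (length(queue) > 0) {
    t <- queue[1]; queue <- queue[-1]
    if (t %in% anc) next
    anc <- c(anc, t)
    queue <- c(queue, onto$parents[[t]])
  }
  anc
}
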
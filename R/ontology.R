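# OBO ontology parsing and navigation of the is-a DAG.
#
# No OBO reader exists in the R dependency stack used here, so a minimal
# parser for the OBO 1.2/1.4 flat format is implemented directly: [Term]
# stanzas with id / name / synonym / is_a / is_obsolete keys. Only is_a
# relations become edges; part_of (a relationship: line) can be enabled.

#' Construct an ontology graph
#'
#' @param terms Character vector of term ids (CURIEs, e.g. `MONDO:0100096`).
#' @param parents Named list mapping each term id to the character vector of
#'   its direct is-a parents (empty for roots).
#' @param names Optional named character vector of term names.
#' @param synonyms Optional named list of character vectors of synonyms.
#' @return An `onto_graph` object.
#' @export
onto_graph <- function(terms, parents, names = NULL, synonyms = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term ids")
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else as.character(p))
  bad <- setdiff(unlist(parents, use.names = FALSE), terms)
  if (length(bad)) {
    stop("is_a edge(s) point to unknown term id(s): ", paste(bad, collapse = ", "))
  }
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) children[[t]] <- character(0)
  for (t in terms) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  g <- structure(
    list(terms = terms, parents = parents, children = children,
         names = names, synonyms = synonyms),
    class = "onto_graph"
  )
  cyc <- .find_cycle(g)
  if (!is.null(cyc)) {
    stop("ontology contains an is_a cycle: ", paste(cyc, collapse = " -> "))
  }
  g
}

# Kahn topological sort; returns one cycle (as a term-id path) or NULL.
.find_cycle <- function(g) {
  indeg <- vapply(g$terms, function(t) length(g$parents[[t]]), integer(1))
  queue <- g$terms[indeg == 0]
  remaining <- indeg
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    for (ch in g$children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  left <- names(remaining)[remaining > 0]
  if (!length(left)) return(NULL)
  # walk parent pointers within the residual set until a node repeats
  path <- left[1]
  repeat {
    nxt <- intersect(g$parents[[path[length(path)]]], left)[1]
    if (nxt %in% path) {
      cyc <- c(path[seq(match(nxt, path), length(path))], nxt)
      return(cyc)
    }
    path <- c(path, nxt)
  }
}

#' @method print onto_graph
#' @export
print.onto_graph <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat("<onto_graph: ", length(x$terms), " terms, ", n_edges, " is_a edges>\n",
      sep = "")
  invisible(x)
}

#' Parse an OBO flat file into an ontology graph
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file. Obsolete terms
#' (`is_obsolete: true`) are excluded together with any edge touching them.
#' Only `is_a` relations become edges unless `include_part_of = TRUE`, in
#' which case `relationship: part_of` lines are added as edges too.
#' A cycle among the retained edges is an error (one cycle is reported).
#'
#' @param path Path to an OBO file.
#' @param include_part_of Also treat `part_of` relationships as edges.
#' @return An `onto_graph` object.
#' @export
load_obo <- function(path, include_part_of = FALSE) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur, stanzas) {
    if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <- cur
    stanzas
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^\\[", ln)) {
      stanzas <- flush(cur, stanzas)
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(id = NA_character_, name = NA_character_,
                               is_a = character(0), part_of = character(0),
                               synonyms = character(0), obsolete = FALSE)
      next
    }
    if (!in_term || !nzchar(ln)) next
    key <- sub(":.*$", "", ln)
    val <- sub("^[^:]+:\\s*", "", ln)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comment
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "is_obsolete" && grepl("^true", val)) cur$obsolete <- TRUE
    else if (key == "synonym") {
      m <- regmatches(val, regexpr('"[^"]*"', val))
      if (length(m)) cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        cur$part_of <- c(cur$part_of, parts[2])
      }
    }
  }
  stanzas <- flush(cur, stanzas)
  if (!length(stanzas)) stop("no [Term] stanzas found in ", path)
  no_id <- vapply(stanzas, function(s) is.na(s$id) || !nzchar(s$id), logical(1))
  if (any(no_id)) stop("OBO [Term] stanza without an id (stanza ",
                       paste(which(no_id), collapse = ", "), ")")
  obsolete <- vapply(stanzas, `[[`, logical(1), "obsolete")
  stanzas <- stanzas[!obsolete]
  if (!length(stanzas)) stop("all [Term] stanzas in ", path, " are obsolete")
  ids <- vapply(stanzas, `[[`, character(1), "id")
  keep <- ids
  parents <- lapply(stanzas, function(s) {
    p <- s$is_a
    if (include_part_of) p <- c(p, s$part_of)
    intersect(unique(p), keep)  # edges into obsolete/unknown terms dropped
  })
  names(parents) <- ids
  nms <- stats::setNames(vapply(stanzas, `[[`, character(1), "name"), ids)
  syns <- stats::setNames(lapply(stanzas, `[[`, "synonyms"), ids)
  onto_graph(ids, parents, names = nms, synonyms = syns)
}

#' Descendants of a term, including the term itself
#'
#' @param g An `onto_graph`.
#' @param term A term id present in `g`.
#' @return Character vector of term ids closed under the child relation.
#' @export
descendants_or_self <- function(g, term) {
  if (!(term %in% g$terms)) stop("unknown term id: ", term)
  seen <- character(0)
  stack <- term
  while (length(stack)) {
    t <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, g$children[[t]])
  }
  sort(seen)
}

#' Ancestors of a term, including the term itself
#'
#' @inheritParams descendants_or_self
#' @return Character vector of term ids closed under the parent relation.
#' @export
ancestors_or_self <- function(g, term) {
  if (!(term %in% g$terms)) stop("unknown term id: ", term)
  seen <- character(0)
  stack <- term
  while (length(stack)) {
    t <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, g$parents[[t]])
  }
  sort(seen)
}

#' Information content of an ontology term
#'
#' Term specificity measured as
#' \deqn{IC(t) = -\log_2\left(\frac{|desc(t)|}{|T|}\right)}
#' where \eqn{desc(t)} are the descendants of \eqn{t} including \eqn{t}
#' itself and \eqn{T} is the full term set. A root covering every term has
#' IC 0; IC grows as the descendant set shrinks, so leaf-proximal (specific)
#' terms score highest.
#'
#' @inheritParams descendants_or_self
#' @return Non-negative IC in bits.
#' @export
information_content <- function(g, term) {
  if (!length(g$terms)) stop("empty ontology")
  n_desc <- length(descendants_or_self(g, term))
  -log2(n_desc / length(g$terms))
}

#' Propagate instance annotations to ancestor terms
#'
#' An instance annotated to a term is treated as a positive example for that
#' term and for every ancestor along is-a paths (the standard true-path
#' rule). Instance sets are deduplicated.
#'
#' @param annotations Data frame with columns `instance_id` and `term_id`
#'   (or a list of such pairs).
#' @param g An `onto_graph`.
#' @return Named list mapping term id to a character vector of positive
#'   instance ids (sorted); terms with no positives are absent.
#' @export
propagate_labels <- function(annotations, g) {
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (nrow(ann) == 0) return(stats::setNames(list(), character(0)))
  bad <- setdiff(unique(ann$term_id), g$terms)
  if (length(bad)) {
    stop("annotation(s) to unknown term id(s): ", paste(bad, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(ann))) {
    for (t in ancestors_or_self(g, ann$term_id[i])) {
      out[[t]] <- c(out[[t]], ann$instance_id[i])
    }
  }
  lapply(out, function(v) sort(unique(v)))
}
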
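#' Load an ontology from an OBO flat file
#'
#' Parses \code{[Term]} stanzas of an OBO file, keeping the \code{id},
#' \code{name}, \code{is_a}, \code{alt_id} and \code{is_obsolete} tags.
#' Obsolete terms are dropped; only \code{is_a} (subsumption) relations are
#' retained, so the resulting graph is the ontology restricted to its
#' subclass hierarchy. \code{alt_id} entries are recorded as aliases that
#' resolve silently to their primary identifier.
#'
#' @param path Path to an OBO file.
#' @return An object of class \code{ontology_graph}: a list with
#'   \item{terms}{character vector of term ids (non-obsolete).}
#'   \item{names}{named character vector mapping id to display name.}
#'   \item{parents}{named list mapping each id to its direct \code{is_a}
#'     parents (character vector, possibly empty).}
#'   \item{children}{named list, the reverse of \code{parents}.}
#'   \item{roots}{ids with no parents (usually the single ontology root).}
#'   \item{alt_ids}{named character vector mapping alternate id to primary id.}
#'   \item{ancestors}{named list with the precomputed ancestor closure
#'     (excluding self, excluding nothing else) of every term.}
#' @details A cycle among \code{is_a} edges or an \code{is_a} target that is
#'   never declared as a term is a hard error. The ancestor closure is
#'   precomputed once at load time by traversal in reverse topological order.
#' @examples
#' obo <- system.file("extdata", "mini_hp.obo", package = "emrpheno")
#' g <- load_ontology(obo)
#' g
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  ids <- character()
  nms <- character()
  parents <- list()
  alt <- character()
  obsolete <- character()

  cur_id <- NA_character_
  cur_name <- NA_character_
  cur_parents <- character()
  cur_alt <- character()
  cur_obs <- FALSE
  in_term <- FALSE

  flush <- function() {
    if (is.na(cur_id)) return()
    if (cur_obs) {
      obsolete[[length(obsolete) + 1L]] <<- cur_id
    } else {
      ids[[length(ids) + 1L]] <<- cur_id
      nms[[cur_id]] <<- if (is.na(cur_name)) cur_id else cur_name
      parents[[cur_id]] <<- unique(cur_parents)
      if (length(cur_alt)) {
        a <- rep(cur_id, length(cur_alt))
        names(a) <- cur_alt
        alt <<- c(alt, a)
      }
    }
  }

  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", ln)          # trailing OBO comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur_id <- NA_character_; cur_name <- NA_character_
      cur_parents <- character(); cur_alt <- character(); cur_obs <- FALSE
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { flush(); cur_id <- NA_character_; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) cur_id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur_name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_a:", ln)) {
      tgt <- trimws(sub("^is_a:", "", ln))
      tgt <- strsplit(tgt, "\\s+")[[1L]][1L]
      cur_parents <- c(cur_parents, tgt)
    }
    else if (grepl("^alt_id:", ln)) cur_alt <- c(cur_alt, trimws(sub("^alt_id:", "", ln)))
    else if (grepl("^is_obsolete:", ln)) {
      cur_obs <- identical(trimws(sub("^is_obsolete:", "", ln)), "true")
    }
  }
  flush()

  if (!length(ids)) stop("no [Term] stanzas found in ", path)
  if (anyDuplicated(ids)) stop("duplicate term id in OBO file: ",
                               ids[duplicated(ids)][1L])

  # parents of retained terms must themselves be retained terms
  for (id in ids) {
    p <- parents[[id]]
    p <- p[!(p %in% obsolete)]           # edges into obsolete terms dropped
    bad <- setdiff(p, ids)
    if (length(bad)) stop("term ", id, " has is_a parent not declared in file: ",
                          paste(bad, collapse = ", "))
    parents[[id]] <- p
  }

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)

  # topological order (children after parents); detects cycles
  indeg <- vapply(parents, length, integer(1))
  queue <- ids[indeg == 0L]
  topo <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(ids)) {
    off <- setdiff(ids, topo)[1L]
    stop("cycle detected among is_a edges; involves edge ", off, " -> ",
         parents[[off]][1L])
  }

  anc <- stats::setNames(vector("list", length(ids)), ids)
  for (v in topo) {
    ps <- parents[[v]]
    anc[[v]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }

  structure(list(
    terms = ids,
    names = nms,
    parents = parents,
    children = children,
    roots = ids[vapply(parents, length, integer(1)) == 0L],
    alt_ids = alt,
    ancestors = anc
  ), class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", length(x$terms), " terms, ",
      sum(vapply(x$parents, length, integer(1))), " is_a edges; root(s): ",
      paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Resolve a possibly-alternate id to its primary id; error on unknown ids.
resolve_term <- function(graph, term) {
  out <- term
  is_alt <- term %in% names(graph$alt_ids)
  out[is_alt] <- graph$alt_ids[term[is_alt]]
  unknown <- setdiff(out, graph$terms)
  if (length(unknown)) stop("unknown ontology term id(s): ",
                            paste(unknown, collapse = ", "))
  out
}

#' Ancestor closure of a term
#'
#' All terms reachable from \code{term} by following \code{is_a} edges
#' upward. The ontology root (any term without parents) is excluded: it is
#' carried by every individual and carries no information.
#'
#' @param graph An \code{ontology_graph}.
#' @param term A single term id (alternate ids are resolved).
#' @param include_self Include \code{term} itself in the returned set?
#' @return Character vector of term ids (a set: no duplicates).
#' @export
ancestors <- function(graph, term, include_self = FALSE) {
  stopifnot(inherits(graph, "ontology_graph"), length(term) == 1L)
  term <- resolve_term(graph, term)
  out <- setdiff(graph$ancestors[[term]], graph$roots)
  if (include_self && !(term %in% graph$roots)) out <- unique(c(term, out))
  out
}

#' Propagate a term set to its ancestral closure
#'
#' Augments a set of assigned terms with every ancestral (higher-level) term
#' so that shared broader clinical concepts become directly comparable across
#' individuals. The ontology root is excluded; all other high-level terms
#' (e.g. a "Phenotypic abnormality"-type sub-root) are retained. The
#' operation is idempotent and its result is closed under \code{ancestors}.
#'
#' @param graph An \code{ontology_graph}.
#' @param terms Character vector of term ids (may be empty).
#' @return Character vector: the union of the input terms and all their
#'   ancestors, root excluded.
#' @export
propagate <- function(graph, terms) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!length(terms)) return(character(0))
  terms <- resolve_term(graph, terms)
  out <- unique(c(terms, unlist(graph$ancestors[terms], use.names = FALSE)))
  setdiff(out, graph$roots)
}

#' Test membership in an ontology branch
#'
#' True iff any of \code{branch_roots} lies in the ancestor closure of
#' \code{term} (including \code{term} itself). Used to exclude modifier
#' branches (clinical modifier, clinical course) from association testing.
#'
#' @param graph An \code{ontology_graph}.
#' @param term A single term id.
#' @param branch_roots Character vector of branch-root term ids.
#' @return Logical scalar.
#' @export
in_branch <- function(graph, term, branch_roots) {
  stopifnot(inherits(graph, "ontology_graph"), length(term) == 1L)
  term <- resolve_term(graph, term)
  branch_roots <- resolve_term(graph, branch_roots)
  any(branch_roots %in% c(term, graph$ancestors[[term]]))
}

#' Default modifier branch roots
#'
#' Term ids of the clinical-modifier and clinical-course branches, whose
#' descendants describe onset, severity or quality of a phenotype rather
#' than a phenotype itself and are excluded from association testing.
#' Override via the \code{modifier_roots} argument of [gxp_scan()].
#'
#' @return Character vector of term ids.
#' @export
default_modifier_roots <- function() c("HP:0012823", "HP:0031797")
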
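#' Construct and validate a causal model (DAG)
#'
#' A causal model is a directed acyclic graph over named variables; edges
#' point from cause to effect. Construction validates the graph: every edge
#' endpoint must be a declared vertex, vertex names must be unique, and the
#' graph must be acyclic (a cycle is reported with one offending path).
#'
#' @param name Model name.
#' @param vertices Character vector of variable names.
#' @param edges Two-column matrix / data frame, or list of length-2 vectors,
#'   of `c(from, to)` pairs.
#' @return An object of class `causal_model` with elements `name`,
#'   `vertices`, `edges` (tibble with `from`, `to`). Supports [tidy()].
#' @examples
#' causal_model("chain", c("X", "Y", "Z"), list(c("X", "Y"), c("Y", "Z")))
#' @export
causal_model <- function(name, vertices, edges) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) {
    abort("Vertex names must be unique.", class = "photolim_invalid_model")
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    if (length(edges) == 0) {
      edges <- tibble(from = character(), to = character())
    } else {
      if (any(lengths(edges) != 2)) {
        abort("Each edge must be a length-2 c(from, to) pair.",
              class = "photolim_invalid_model")
      }
      edges <- tibble(from = vapply(edges, `[`, "", 1),
                      to = vapply(edges, `[`, "", 2))
    }
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges) <- c("from", "to")
    edges <- as_tibble(edges)
    edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  }
  model <- structure(list(name = name, vertices = vertices, edges = edges),
                     class = "causal_model")
  validate_dag(model)
}

#' @rdname causal_model
#' @param model A `causal_model` (or plain list with `name`, `vertices`,
#'   `edges`).
#' @export
validate_dag <- function(model) {
  vertices <- model$vertices
  edges <- model$edges
  unknown <- setdiff(c(edges$from, edges$to), vertices)
  if (length(unknown) > 0) {
    abort(sprintf("Edge endpoint%s not declared as vertices: %s.",
                  if (length(unknown) > 1) "s" else "",
                  paste(unique(unknown), collapse = ", ")),
          class = "photolim_invalid_model")
  }
  if (any(edges$from == edges$to)) {
    abort("Self-loops are not allowed.", class = "photolim_cyclic_model")
  }
  cyc <- find_cycle(vertices, edges)
  if (!is.null(cyc)) {
    abort(sprintf("Model '%s' is cyclic: %s.", model$name,
                  paste(cyc, collapse = " -> ")),
          class = "photolim_cyclic_model")
  }
  if (!inherits(model, "causal_model")) class(model) <- "causal_model"
  model
}

# Kahn topological sort; returns NULL if acyclic, else one cycle as a
# vertex path c(v1, ..., v1).
find_cycle <- function(vertices, edges) {
  indeg <- setNames(integer(length(vertices)), vertices)
  for (v in edges$to) indeg[v] <- indeg[v] + 1
  queue <- names(indeg)[indeg == 0]
  remaining <- edges
  seen <- character()
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; seen <- c(seen, v)
    out <- remaining$to[remaining$from == v]
    remaining <- remaining[remaining$from != v, , drop = FALSE]
    for (w in out) {
      indeg[w] <- indeg[w] - 1
      if (indeg[w] == 0) queue <- c(queue, w)
    }
  }
  if (length(seen) == length(vertices)) return(NULL)
  # walk the leftover subgraph (all its vertices lie on or lead into a cycle)
  inside <- setdiff(vertices, seen)
  path <- inside[1]
  repeat {
    nxt <- remaining$to[remaining$from == path[length(path)]][1]
    if (nxt %in% path) {
      cycle <- path[seq(match(nxt, path), length(path))]
      return(c(cycle, nxt))
    }
    path <- c(path, nxt)
  }
}

topological_order <- function(model) {
  vertices <- model$vertices; edges <- model$edges
  indeg <- setNames(integer(length(vertices)), vertices)
  for (v in edges$to) indeg[v] <- indeg[v] + 1
  order <- character()
  queue <- sort(names(indeg)[indeg == 0])
  remaining <- edges
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; order <- c(order, v)
    out <- remaining$to[remaining$from == v]
    remaining <- remaining[remaining$from != v, , drop = FALSE]
    for (w in out) {
      indeg[w] <- indeg[w] - 1
      if (indeg[w] == 0) queue <- sort(c(queue, w))
    }
  }
  order
}

parents_of <- function(model, v) {
  sort(model$edges$from[model$edges$to == v])
}

#' Union basis set of independence claims implied by a DAG
#'
#' One claim per non-adjacent vertex pair (x, y): x is independent of y given
#' the union of both vertices' parent sets (minus x and y themselves). The
#' set has exactly choose(v, 2) - |edges| claims and is returned in
#' lexicographic pair order, so the degrees of freedom of the combined test
#' are 2 x number of claims.
#'
#' @param model A validated [causal_model()].
#' @return A tibble with columns `x`, `y` and `conditioning_set`
#'   (list column of character vectors).
#' @examples
#' m <- causal_model("chain", c("X", "Y", "Z"), list(c("X", "Y"), c("Y", "Z")))
#' basis_set(m)
#' @export
basis_set <- function(model) {
  model <- validate_dag(model)
  v <- sort(model$vertices)
  adjacent <- paste(pmin(model$edges$from, model$edges$to),
                    pmax(model$edges$from, model$edges$to))
  claims <- list(); xs <- character(); ys <- character()
  for (i in seq_along(v)) {
    for (j in seq_along(v)) {
      if (j <= i) next
      x <- v[i]; y <- v[j]
      if (paste(x, y) %in% adjacent) next
      cond <- setdiff(union(parents_of(model, x), parents_of(model, y)),
                      c(x, y))
      xs <- c(xs, x); ys <- c(ys, y)
      claims[[length(claims) + 1]] <- sort(cond)
    }
  }
  tibble(x = xs, y = ys, conditioning_set = claims)
}

#' @export
print.causal_model <- function(x, ...) {
  cat(sprintf("Causal model '%s': %d vertices, %d edges\n",
              x$name, length(x$vertices), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read a causal model from JSON or YAML
#'
#' Model files carry keys `name`, `vertices` and `edges` (a list of
#' `[from, to]` pairs). The format is chosen from the file extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return A validated [causal_model()].
#' @export
read_causal_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    abort(sprintf("Unsupported model file extension '.%s' (use .json/.yaml).", ext),
          class = "photolim_invalid_input")
  )
  for (key in c("name", "vertices", "edges")) {
    if (is.null(parsed[[key]])) {
      abort(sprintf("Model file is missing key '%s'.", key),
            class = "photolim_invalid_model")
    }
  }
  causal_model(parsed$name, unlist(parsed$vertices), parsed$edges)
}

#' The built-in acyclic expression-physiology model
#'
#' The package's fixture DAG over aquaporin expression (PIP1, PIP2), stomatal
#' and mesophyll conductance, net assimilation and carbonic anhydrase
#' expression: PIP1 -> PIP2, PIP1 -> gs, PIP2 -> gs, PIP2 -> gm, gs -> AN,
#' gm -> AN, AN -> CA. This is the CA-feedback physiological model with the
#' CA -> gm edge removed: with it, gm -> AN -> CA -> gm closes a directed
#' cycle, which d-separation cannot test.
#'
#' @return A validated [causal_model()] named `"model3_acyclic"`.
#' @export
model3_acyclic <- function() {
  causal_model(
    "model3_acyclic",
    c("PIP1", "PIP2", "gs", "gm", "AN", "CA"),
    list(c("PIP1", "PIP2"), c("PIP1", "gs"), c("PIP2", "gs"),
         c("PIP2", "gm"), c("gs", "AN"), c("gm", "AN"), c("AN", "CA"))
  )
}
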
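# Hierarchical (multi-level, multi-attribute) evidence fusion over a
# directory tree.
#
# The directory layout mirrors the assessment framework. Every folder is
# one attribute node and holds a combined-results file named
# "<FolderName>_combined.csv"; internal folders additionally hold one
# subfolder per sub-attribute, while leaf folders hold one or more
# evidence files matching "Evidence*.csv". All files store data for ALL
# assessed objects: one row per object, a Weight column, then one column
# per proposition. In a combined file the Weight column carries the
# node's importance among its siblings (constant down the column); in an
# evidence file it carries that evidence source's weight. The
# conventional root folder name is "Objects", giving the root output file
# "Objects_combined.csv", but any root name is accepted.
#
# Fusion is bottom-up, per object: each leaf fuses its evidence rows with
# the ER combination; each internal node then treats every child's fused
# distribution as one body of evidence -- the child's residual uncertainty
# is carried upward as incompleteness of that body -- weighted by the
# child's sibling weight (normalized within the parent).

combined_file <- function(path) {
  file.path(path, paste0(basename(path), "_combined.csv"))
}

# Read a combined or evidence file: per-object rows, a constant Weight
# column, proposition columns. A trailing Uncertainty column (present
# after a previous fusion run) is dropped on input.
read_node_table <- function(path) {
  parsed <- parse_belief_table(read_raw_table(path), path)
  if (tolower(parsed$props[length(parsed$props)]) == "uncertainty") {
    keep <- seq_len(length(parsed$props) - 1L)
    parsed$beliefs <- parsed$beliefs[, keep, drop = FALSE]
    parsed$props <- parsed$props[keep]
  }
  w <- parsed$weights
  if (length(w) > 1L && any(abs(w - w[1L]) > 1e-9))
    er_abort("validation",
             sprintf("Weight column must be constant in %s", path))
  list(objects = parsed$labels, weight = w[1L], beliefs = parsed$beliefs,
       props = parsed$props, source = path)
}

check_node_consistency <- function(tab, objects, props, ref_source) {
  if (!identical(tab$objects, objects))
    er_abort("validation",
             sprintf("object list in %s differs from %s (order-sensitive)",
                     tab$source, ref_source))
  if (!identical(tab$props, props))
    er_abort("validation",
             sprintf("proposition headers in %s differ from %s",
                     tab$source, ref_source))
  invisible(tab)
}

load_node <- function(path, objects, props, ref_source) {
  cf <- combined_file(path)
  if (!file.exists(cf))
    er_abort("validation",
             sprintf("missing combined file %s in folder %s",
                     basename(cf), path))
  tab <- read_node_table(cf)
  if (is.null(objects)) {       # root fixes the reference order
    objects <- tab$objects
    props <- tab$props
    ref_source <- cf
  } else {
    check_node_consistency(tab, objects, props, ref_source)
  }
  subdirs <- sort(list.dirs(path, recursive = FALSE))
  node <- list(name = basename(path), path = path, weight = tab$weight,
               objects = objects, props = props)
  if (length(subdirs) > 0L) {
    node$children <- lapply(subdirs, load_node, objects = objects,
                            props = props, ref_source = ref_source)
  } else {
    efiles <- sort(list.files(path, pattern = "^Evidence.*\\.csv$",
                              full.names = TRUE))
    if (length(efiles) == 0L)
      er_abort("validation",
               sprintf("leaf folder %s contains no Evidence*.csv files",
                       path))
    node$evidence <- lapply(efiles, function(f)
      check_node_consistency(read_node_table(f), objects, props,
                             ref_source))
  }
  node
}

#' Load a multi-level assessment tree from a directory
#'
#' Walks a directory tree whose structure mirrors a multi-level
#' multi-attribute assessment framework (see the package vignette for the
#' file layout) and validates that every file shares the same ordered
#' object list and proposition headers.
#'
#' @param path Root folder of the tree (conventionally named `Objects`).
#' @return An object of class `attribute_tree` with elements `root` (the
#'   nested node structure), `frame`, and `objects`.
#' @export
load_tree_from_directory <- function(path) {
  if (!dir.exists(path))
    er_abort("io", sprintf("directory not found: %s", path))
  root <- load_node(normalizePath(path), NULL, NULL, NULL)
  structure(list(root = root, frame = er_frame(root$props),
                 objects = root$objects),
            class = "attribute_tree")
}

#' @export
print.attribute_tree <- function(x, ...) {
  cat(sprintf("<attribute_tree: root '%s', %d objects, %d propositions>\n",
              x$root$name, length(x$objects), x$frame$N))
  show_node <- function(node, indent) {
    kind <- if (is.null(node$children))
      sprintf("leaf, %d evidence file(s)", length(node$evidence))
    else sprintf("%d children", length(node$children))
    cat(sprintf("%s- %s (weight %g, %s)\n", indent, node$name, node$weight,
                kind))
    for (ch in node$children %||% list()) show_node(ch, paste0(indent, "  "))
  }
  show_node(x$root, " ")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Annotate engine errors with the node path and object label.
with_fusion_context <- function(expr, node_path, object) {
  tryCatch(expr, erfusion_error = function(e) {
    er_abort(e$code,
             sprintf("%s [node %s, object '%s']", conditionMessage(e),
                     node_path, object),
             step = e$step)
  })
}

fuse_node <- function(node, frame, rel_path, results) {
  n_obj <- length(node$objects)
  if (!is.null(node$children)) {
    child_mats <- lapply(node$children, function(ch)
      fuse_node(ch, frame, paste(rel_path, ch$name, sep = "/"), results))
    weights <- vapply(node$children, function(ch) ch$weight, 0)
    mat <- matrix(0, n_obj, frame$N + 1L)
    for (o in seq_len(n_obj)) {
      bodies <- lapply(child_mats, function(cm)
        evidence_body(cm[o, seq_len(frame$N)], frame, tol = 1e-9))
      res <- with_fusion_context(
        er_fuse(bodies, weights, frame), rel_path, node$objects[o])
      mat[o, ] <- c(res$beliefs, res$uncertainty)
    }
  } else {
    weights <- vapply(node$evidence, function(tab) tab$weight, 0)
    mat <- matrix(0, n_obj, frame$N + 1L)
    for (o in seq_len(n_obj)) {
      bodies <- lapply(node$evidence, function(tab)
        evidence_body(tab$beliefs[o, ], frame,
                      label = basename(tab$source)))
      res <- with_fusion_context(
        er_fuse(bodies, weights, frame), rel_path, node$objects[o])
      mat[o, ] <- c(res$beliefs, res$uncertainty)
    }
  }
  dimnames(mat) <- list(node$objects, c(frame$propositions, "Uncertainty"))
  results[[rel_path]] <- mat
  mat
}

#' Fuse all evidence in an assessment tree
#'
#' Performs bottom-up, per-object ER fusion: leaves fuse their evidence
#' files' rows; each internal node fuses its children's results, carrying
#' a child's residual uncertainty upward as incompleteness and using the
#' children's sibling weights (normalized within the parent).
#'
#' @param tree An [attribute_tree][load_tree_from_directory].
#' @return A named list of matrices (objects x propositions +
#'   `Uncertainty`), one per node, keyed by the node's path relative to
#'   the root (e.g. `"Objects"`, `"Objects/Research"`); the root entry
#'   holds the final result.
#' @export
fuse_tree <- function(tree) {
  if (!inherits(tree, "attribute_tree"))
    er_abort("validation", "fuse_tree expects an attribute_tree")
  results <- new.env(parent = emptyenv())
  fuse_node(tree$root, tree$frame, tree$root$name, results)
  out <- as.list(results)
  out[order(names(out))]
}

#' Write fused results back into the tree's combined files
#'
#' Rewrites every node's `<name>_combined.csv` with the fused belief
#' degrees: objects as rows, proposition columns, the node's Weight
#' column preserved, plus an `Uncertainty` column. The root file is the
#' tree's final output (conventionally `Objects_combined.csv`). Writing
#' is deterministic, so repeated runs reproduce identical files.
#'
#' @param tree An [attribute_tree][load_tree_from_directory].
#' @param results The list returned by [fuse_tree()].
#' @return Character vector of written file paths, invisibly.
#' @export
write_combined_files <- function(tree, results) {
  written <- character(0)
  walk <- function(node, rel_path) {
    mat <- results[[rel_path]]
    if (is.null(mat))
      er_abort("validation",
               sprintf("no fused results for node %s", rel_path))
    df <- cbind(data.frame(Object = node$objects, Weight = node$weight,
                           check.names = FALSE),
                as.data.frame(mat, check.names = FALSE))
    names(df)[1L] <- "Object"
    target <- combined_file(node$path)
    ok <- tryCatch({
      utils::write.csv(df, target, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      er_abort("io", sprintf("cannot write %s: %s", target,
                             conditionMessage(ok)))
    written <<- c(written, target)
    for (ch in node$children %||% list())
      walk(ch, paste(rel_path, ch$name, sep = "/"))
  }
  walk(tree$root, tree$root$name)
  invisible(written)
}

#' Load, fuse and write a multi-level assessment tree in one call
#'
#' Convenience wrapper chaining [load_tree_from_directory()],
#' [fuse_tree()] and (optionally) [write_combined_files()].
#'
#' @param path Root folder of the tree.
#' @param write Rewrite the combined files with the fused results
#'   (default `TRUE`).
#' @return The [fuse_tree()] result list, invisibly.
#' @export
multilevel_fuse <- function(path, write = TRUE) {
  tree <- load_tree_from_directory(path)
  results <- fuse_tree(tree)
  if (write) write_combined_files(tree, results)
  invisible(results)
}
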
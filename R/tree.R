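#' Canonical document trees
#'
#' All register payloads, whatever their wire format, are held in one nested
#' representation: JSON-style trees in which an *object* is a named list, an
#' *array* is an unnamed list, and a *leaf* is an atomic scalar. XML is mapped
#' onto this convention deterministically: repeated sibling elements become
#' ordered arrays, attributes become fields prefixed with `"@"`, and mixed
#' content (non-blank text alongside child elements) is rejected.
#'
#' @name document-trees
#' @keywords internal
NULL

is_array_node <- function(x) {
  is.list(x) && (is.null(names(x)) || all(names(x) == ""))
}

is_object_node <- function(x) {
  is.list(x) && !is.null(names(x)) && any(names(x) != "")
}

#' Parse a JSON payload into a document tree
#'
#' @param text JSON text (one record or an array of records).
#' @return A nested list: named lists for objects, unnamed lists for arrays.
#' @export
json_to_tree <- function(text) {
  jsonlite::fromJSON(text, simplifyVector = FALSE)
}

#' Parse an XML payload into a document tree
#'
#' Repeated sibling elements collapse into an ordered unnamed list; attributes
#' become `"@"`-prefixed fields; an element holding both non-blank text and
#' child elements is an error (mixed content has no stable tree form).
#'
#' @param x XML text or an `xml2` document/node.
#' @return A nested list in the canonical tree convention.
#' @export
xml_to_tree <- function(x) {
  if (inherits(x, "xml_node") || inherits(x, "xml_document")) {
    node <- if (inherits(x, "xml_document")) xml2::xml_root(x) else x
  } else {
    node <- xml2::xml_root(xml2::read_xml(x))
  }
  xml_node_to_tree(node)
}

xml_node_to_tree <- function(node) {
  kids <- xml2::xml_children(node)
  attrs <- xml2::xml_attrs(node)
  if (length(kids) == 0) {
    txt <- trimws(xml2::xml_text(node))
    if (length(attrs) == 0) return(if (nzchar(txt)) txt else NULL)
    out <- as.list(attrs)
    names(out) <- paste0("@", names(attrs))
    if (nzchar(txt)) out[["#text"]] <- txt
    return(out)
  }
  direct_text <- trimws(paste(xml2::xml_text(xml2::xml_find_all(node, "text()")), collapse = ""))
  if (nzchar(direct_text)) {
    abort(
      sprintf("mixed content in element <%s> is not supported", xml2::xml_name(node)),
      class = "regharvest_parse_error"
    )
  }
  out <- list()
  if (length(attrs) > 0) {
    a <- as.list(attrs)
    names(a) <- paste0("@", names(attrs))
    out <- a
  }
  nms <- xml2::xml_name(kids)
  for (nm in unique(nms)) {
    sub <- lapply(which(nms == nm), function(i) xml_node_to_tree(kids[[i]]))
    out[[nm]] <- if (length(sub) > 1) unname(sub) else sub[[1]]
  }
  out
}

# All dotted leaf paths present in a tree (arrays traversed implicitly,
# no positional indices in the path itself).
tree_paths <- function(tree) {
  out <- character(0)
  rec <- function(node, prefix) {
    if (is.null(node)) return(invisible(NULL))
    if (is_array_node(node)) {
      for (el in node) rec(el, prefix)
    } else if (is.list(node)) {
      for (nm in names(node)) rec(node[[nm]], c(prefix, nm))
    } else if (length(prefix) > 0) {
      out[[length(out) + 1]] <<- paste(prefix, collapse = ".")
    }
    invisible(NULL)
  }
  rec(tree, character(0))
  sort(unique(unlist(out)))
}

# Extract the value at a dotted path, preserving array nesting: each array
# crossed contributes one list level in the result. Absent path -> NULL.
tree_extract <- function(tree, path) {
  components <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(node, comps) {
    if (is.null(node)) return(NULL)
    if (is_array_node(node)) {
      return(lapply(node, rec, comps))
    }
    if (length(comps) == 0) {
      # leaf reached; a remaining subtree is not addressable by a leaf path
      return(if (is.list(node)) NULL else node)
    }
    if (!is.list(node)) return(NULL)
    rec(node[[comps[1]]], comps[-1])
  }
  rec(tree, components)
}

# Enumerate leaves of an extraction as (identifier, value) pairs, identifier
# being the dotted positional index through the arrays crossed ("" depth 0 is
# reported as "1" per the long-format convention).
extraction_leaves <- function(x) {
  ids <- character(0)
  vals <- list()
  rec <- function(node, idx) {
    if (is.null(node)) return(invisible(NULL))
    if (is_array_node(node)) {
      for (i in seq_along(node)) rec(node[[i]], c(idx, i))
    } else if (is.list(node)) {
      invisible(NULL) # named subtree: not a leaf
    } else {
      ids[[length(ids) + 1]] <<- if (length(idx)) paste(idx, collapse = ".") else "1"
      vals[[length(vals) + 1]] <<- node
    }
    invisible(NULL)
  }
  rec(x, integer(0))
  list(identifier = unlist(ids) %||% character(0), value = vals)
}

# Flat vector of leaf values (document order); NULL-free. Homogeneous leaves
# keep their type; mixed-type sequences fall back to character rather than
# let vector coercion mangle values (e.g. FALSE -> 0 next to a number).
extraction_values <- function(x) {
  lv <- extraction_leaves(x)$value
  if (length(lv) == 0) return(NULL)
  types <- unique(vapply(lv, function(v) class(v)[1], character(1)))
  if (length(types) == 1) unlist(lv, use.names = FALSE)
  else vapply(lv, as.character, character(1))
}

# Indented text rendering of a tree: every leaf appears exactly once,
# object keys in insertion order, array elements as "[i]".
tree_render <- function(tree, indent = 0) {
  pad <- strrep("  ", indent)
  lines <- character(0)
  if (is.null(tree)) return(lines)
  if (is_array_node(tree)) {
    for (i in seq_along(tree)) {
      el <- tree[[i]]
      if (is.list(el)) {
        lines <- c(lines, paste0(pad, "[", i, "]"), tree_render(el, indent + 1))
      } else {
        lines <- c(lines, paste0(pad, "[", i, "]: ", format(el)))
      }
    }
  } else if (is.list(tree)) {
    for (nm in names(tree)) {
      el <- tree[[nm]]
      if (is.list(el)) {
        lines <- c(lines, paste0(pad, nm, ":"), tree_render(el, indent + 1))
      } else {
        lines <- c(lines, paste0(pad, nm, ": ", format(el)))
      }
    }
  } else {
    lines <- paste0(pad, format(tree))
  }
  lines
}
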
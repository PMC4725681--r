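NCBI_DIVISION_MAP <- c(
  "0" = "other",          # bacteria
  "1" = "Invertebrates",
  "2" = "Vertebrates",    # mammals
  "3" = "other",          # phages
  "4" = "Plants",         # plants and fungi
  "5" = "Vertebrates",    # primates
  "6" = "Vertebrates",    # rodents
  "7" = "other",          # synthetic
  "8" = "",               # unassigned: defer to the nearest labelled ancestor
  "9" = "Vertebrates",
  "10" = "other",         # viruses
  "11" = "other"          # environmental samples
)

new_taxonomy <- function(nodes) {
  stopifnot(all(c("taxid", "parent", "rank", "name", "division")
                %in% names(nodes)))
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  nodes$division[is.na(nodes$division)] <- ""
  if (anyDuplicated(nodes$taxid)) {
    stop("duplicate taxid: ", nodes$taxid[duplicated(nodes$taxid)][1],
         call. = FALSE)
  }
  root <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (self-parent node); found ",
         length(root), call. = FALSE)
  }
  orphan <- setdiff(nodes$parent, nodes$taxid)
  if (length(orphan) > 0L) {
    stop("parent taxid ", orphan[1], " is missing from the node table",
         call. = FALSE)
  }
  # every node must reach the root (detects cycles)
  parent_of <- stats::setNames(nodes$parent, nodes$taxid)
  for (tx in nodes$taxid) {
    cur <- tx
    for (step in seq_len(nrow(nodes) + 1L)) {
      if (cur == root) break
      cur <- parent_of[[as.character(cur)]]
      if (step > nrow(nodes)) {
        stop("cycle detected in taxonomy at taxid ", tx, call. = FALSE)
      }
    }
    if (cur != root) stop("cycle detected in taxonomy at taxid ", tx,
                          call. = FALSE)
  }
  out <- tibble::as_tibble(nodes[, c("taxid", "parent", "rank", "name",
                                     "division")])
  class(out) <- c("taxonomy", class(out))
  attr(out, "root") <- root
  out
}

#' Load a taxonomy
#'
#' Two dialects are accepted: a simplified lineage TSV with header columns
#' `taxid`, `parent`, `rank`, `name`, `division` (the primary fixture
#' dialect), or NCBI-taxdump-style `nodes.dmp` / `names.dmp` files
#' (`|`-delimited; the numeric division code of `nodes.dmp` is mapped onto
#' Plants / Invertebrates / Vertebrates / other). Both dialects yield
#' identical structures for equivalent content. The root is the unique node
#' that is its own parent; cycles and orphan nodes raise a structural error
#' naming the taxid.
#'
#' @param nodes_path Path to the lineage TSV, or to `nodes.dmp` when
#'   `names_path` is given.
#' @param names_path Optional path to `names.dmp` (taxdump dialect).
#' @return A `taxonomy` object (a tibble of nodes with a root attribute).
#' @export
load_taxonomy <- function(nodes_path, names_path = NULL) {
  if (is.null(names_path)) {
    nodes <- readr::read_tsv(nodes_path, show_col_types = FALSE,
                             col_types = readr::cols(
                               taxid = readr::col_integer(),
                               parent = readr::col_integer(),
                               rank = readr::col_character(),
                               name = readr::col_character(),
                               division = readr::col_character()
                             ))
    nodes$division[is.na(nodes$division)] <- ""
    return(new_taxonomy(nodes))
  }
  split_dmp <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(strsplit(lines, "|", fixed = TRUE), trimws)
  }
  nd <- split_dmp(nodes_path)
  nodes <- tibble::tibble(
    taxid = as.integer(vapply(nd, `[`, character(1), 1L)),
    parent = as.integer(vapply(nd, `[`, character(1), 2L)),
    rank = vapply(nd, `[`, character(1), 3L),
    division = unname(NCBI_DIVISION_MAP[vapply(nd, `[`, character(1), 5L)])
  )
  nodes$division[is.na(nodes$division)] <- ""
  nm <- split_dmp(names_path)
  sci <- Filter(function(f) length(f) >= 4L && f[4] == "scientific name", nm)
  name_map <- stats::setNames(vapply(sci, `[`, character(1), 2L),
                              vapply(sci, `[`, character(1), 1L))
  nodes$name <- unname(name_map[as.character(nodes$taxid)])
  nodes$name[is.na(nodes$name)] <- as.character(nodes$taxid[is.na(nodes$name)])
  new_taxonomy(nodes)
}

#' @rdname load_taxonomy
#' @param nodes A tibble of nodes (`taxid`, `parent`, `rank`, `name`,
#'   `division`) to validate and wrap directly.
#' @export
taxonomy <- function(nodes) new_taxonomy(nodes)

tax_root <- function(tax) attr(tax, "root")

tax_row <- function(tax, taxid) {
  i <- match(as.integer(taxid), tax$taxid)
  if (anyNA(i)) {
    stop("unknown taxid: ", paste(taxid[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Lineage of a taxon, node first, root last
#'
#' @param tax A `taxonomy`.
#' @param taxid A single taxid present in the taxonomy.
#' @return A tibble of the node's ancestors-or-self, ordered node -> root.
#' @export
lineage <- function(tax, taxid) {
  ids <- integer()
  cur <- as.integer(taxid)
  root <- tax_root(tax)
  repeat {
    i <- tax_row(tax, cur)
    ids <- c(ids, cur)
    if (cur == root) break
    cur <- tax$parent[i]
  }
  tax[tax_row(tax, ids), ]
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon -- the
#' "highest taxonomy common to all the species" used for cluster conclusions.
#'
#' @param tax A `taxonomy`.
#' @param taxids Non-empty vector of taxids, all present in the taxonomy.
#' @return A single taxid.
#' @export
lowest_common_ancestor <- function(tax, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) stop("empty taxid set", call. = FALSE)
  tax_row(tax, taxids)  # validates all ids
  common <- lineage(tax, taxids[1])$taxid
  for (tx in taxids[-1]) {
    cur <- tx
    while (!(cur %in% common)) {
      cur <- tax$parent[tax_row(tax, cur)]
    }
    common <- common[which(common == cur):length(common)]
  }
  common[1]
}

#' Division label of a taxon
#'
#' Returns the node's own division when set, otherwise the division of the
#' nearest ancestor carrying one; `"other"` when no ancestor carries a label.
#'
#' @param tax A `taxonomy`.
#' @param taxid A single taxid present in the taxonomy.
#' @return A division label string.
#' @export
division_of <- function(tax, taxid) {
  path <- lineage(tax, taxid)
  hit <- which(nzchar(path$division))
  if (length(hit) == 0L) return("other")
  path$division[hit[1]]
}

#' Scientific name and rank lookups
#' @param tax A `taxonomy`.
#' @param taxid Vector of taxids.
#' @return Character vector of names (or ranks).
#' @export
tax_name <- function(tax, taxid) tax$name[tax_row(tax, taxid)]

#' @rdname tax_name
#' @export
tax_rank <- function(tax, taxid) tax$rank[tax_row(tax, taxid)]
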
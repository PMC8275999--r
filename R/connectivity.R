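# Signed node-strength summaries of effective-connectivity parameter
# tables (directed edge lists with parameter estimates and posterior
# probabilities, the output shape of group-level PEB analyses).

# short-name to full-region canonicalization used by the bundled
# seven-node self-appraisal network
.node_canonical_map <- c(AIns = "rAIns", DLPFC = "lDLPFC", TPJ = "rTPJ")

#' Parse an effective-connectivity parameter table
#'
#' Reads a directed edge list with one row per connection: `source`,
#' `target`, `pe` (parameter estimate: Hz-scaled modulation for
#' between-region edges, log-scaled for self-connections), `pp` (posterior
#' probability), and optionally `contrast`. Alternatively a single `edge`
#' column of the form `"A -> B"` is accepted. Self-connections are tagged.
#' Validation: PP must lie in [0, 1]; at most one row per directed pair per
#' contrast; when a node set is declared, every name must belong to it.
#'
#' @param x Path to a CSV file, or a data frame.
#' @param nodes Optional declared node set (character). If NULL, the set is
#'   the union of observed names.
#' @param canonicalize Replace short region names (AIns, DLPFC, TPJ) with
#'   their lateralised forms (rAIns, lDLPFC, rTPJ). Default TRUE.
#' @return Data frame of class `connectivity_table` with columns `contrast`
#'   (may be absent), `source`, `target`, `pe`, `pp`, `self`; the node set
#'   is stored in `attr(, "nodes")`.
#' @export
parse_connectivity_table <- function(x, nodes = NULL, canonicalize = TRUE) {
  tab <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
         else as.data.frame(x)
  if (!nrow(tab)) stop("empty connectivity table")
  if ("edge" %in% names(tab) && !all(c("source", "target") %in% names(tab))) {
    parts <- strsplit(gsub("→", "->", tab$edge), "->", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("malformed edge column; expected 'A -> B'")
    tab$source <- trimws(vapply(parts, `[`, "", 1))
    tab$target <- trimws(vapply(parts, `[`, "", 2))
  }
  req <- c("source", "target", "pe", "pp")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  tab$pe <- as.numeric(tab$pe)
  tab$pp <- as.numeric(tab$pp)
  if (any(is.na(tab$pp)) || any(tab$pp < 0 | tab$pp > 1))
    stop("posterior probabilities must lie in [0, 1]")
  if (canonicalize) {
    cm <- .node_canonical_map
    tab$source <- ifelse(tab$source %in% names(cm), cm[tab$source], tab$source)
    tab$target <- ifelse(tab$target %in% names(cm), cm[tab$target], tab$target)
  }
  observed <- union(tab$source, tab$target)
  if (is.null(nodes)) nodes <- observed
  else {
    unknown <- setdiff(observed, nodes)
    if (length(unknown))
      stop("unknown node(s): ", paste(unknown, collapse = ", "))
  }
  key <- paste(if ("contrast" %in% names(tab)) tab$contrast else "",
               tab$source, tab$target, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate directed edge: ", gsub("^\\|", "", gsub("\\|", " -> ", dup)))
  }
  tab$self <- tab$source == tab$target
  keep <- intersect(c("contrast", "source", "target", "pe", "pp", "self"),
                    names(tab))
  tab <- tab[, keep]
  attr(tab, "nodes") <- nodes
  class(tab) <- c("connectivity_table", "data.frame")
  tab
}

#' Load the bundled seven-node self-appraisal PEB table
#'
#' Published group-level effective-connectivity parameter estimates for the
#' seven-node self-appraisal network (rAIns, lDLPFC, MPFC, PCC, rTPJ, lPG,
#' rPG): 35 directed parameters per contrast (group mean, POS > others,
#' NEG > others), with posterior probabilities. lPG and rPG are output-only
#' regions (no outgoing rows, no self-connection rows).
#'
#' @param contrast Optional contrast to subset: `"group_mean"`,
#'   `"pos_vs_others"`, or `"neg_vs_others"`.
#' @return A `connectivity_table`.
#' @export
selfappraisal_peb <- function(contrast = NULL) {
  path <- system.file("extdata", "selfappraisal_peb.csv", package = "mepm")
  nodes <- c("rAIns", "lDLPFC", "MPFC", "PCC", "rTPJ", "lPG", "rPG")
  tab <- parse_connectivity_table(path, nodes = nodes, canonicalize = TRUE)
  if (!is.null(contrast)) {
    if (!contrast %in% tab$contrast)
      stop("unknown contrast: ", contrast)
    tab <- tab[tab$contrast == contrast, ]
    attr(tab, "nodes") <- nodes
    class(tab) <- c("connectivity_table", "data.frame")
  }
  tab
}

#' Filter edges by posterior-probability evidence
#'
#' Retains rows with `pp >= threshold`. Conventional presets: 0.75
#' ("positive evidence") and 0.95 ("strong evidence"). Note that node
#' strengths are defined on the unfiltered table; filtering is for
#' reporting which edges carry evidence.
#'
#' @param table A `connectivity_table`.
#' @param threshold Probability in [0, 1], default 0.75.
#' @return The filtered `connectivity_table`.
#' @export
filter_by_pp <- function(table, threshold = 0.75) {
  stopifnot(inherits(table, "connectivity_table"),
            threshold >= 0, threshold <= 1)
  nodes <- attr(table, "nodes")
  out <- table[table$pp >= threshold, ]
  attr(out, "nodes") <- nodes
  class(out) <- c("connectivity_table", "data.frame")
  out
}

#' Signed directed node strengths
#'
#' For each node, the out-strength is the sum of parameter estimates of its
#' outgoing between-region edges and the in-strength the sum over incoming
#' between-region edges; self-connections are excluded from both. For
#' signed networks these balances of excitatory (positive) and inhibitory
#' (negative) connections; total out-strength equals total in-strength on
#' every table. All edges enter regardless of posterior probability.
#'
#' @param table A `connectivity_table` holding a single contrast (subset
#'   with `contrast` if the table carries several).
#' @param contrast Optional contrast to subset before summing.
#' @return Data frame of class `node_strengths`: `node`, `out_strength`,
#'   `in_strength`.
#' @export
node_strengths <- function(table, contrast = NULL) {
  stopifnot(inherits(table, "connectivity_table"))
  nodes <- attr(table, "nodes")
  if (!is.null(contrast)) {
    if (!"contrast" %in% names(table)) stop("table has no contrast column")
    table <- table[table$contrast == contrast, ]
  } else if ("contrast" %in% names(table) &&
             length(unique(table$contrast)) > 1) {
    stop("table holds several contrasts; pass `contrast` to select one")
  }
  between <- table[!table$self, , drop = FALSE]
  out_s <- vapply(nodes, function(nd)
    sum(between$pe[between$source == nd]), numeric(1))
  in_s <- vapply(nodes, function(nd)
    sum(between$pe[between$target == nd]), numeric(1))
  res <- data.frame(node = nodes, out_strength = unname(out_s),
                    in_strength = unname(in_s))
  class(res) <- c("node_strengths", "data.frame")
  res
}

#' Extreme nodes of a strength table
#'
#' Reports the nodes attaining the maximal positive (argmax) and maximal
#' negative (argmin) out- and in-strengths; ties are reported as sets.
#'
#' @param strengths A `node_strengths` data frame.
#' @param tol Absolute tolerance for declaring a tie, default 1e-12.
#' @return List with elements `max_pos_out`, `max_neg_out`, `max_pos_in`,
#'   `max_neg_in`, each a list `nodes` (character) and `value`.
#' @export
extreme_nodes <- function(strengths, tol = 1e-12) {
  stopifnot(inherits(strengths, "node_strengths"), nrow(strengths) >= 1)
  pick <- function(v, fun) {
    val <- fun(v)
    list(nodes = strengths$node[abs(v - val) <= tol], value = val)
  }
  list(max_pos_out = pick(strengths$out_strength, max),
       max_neg_out = pick(strengths$out_strength, min),
       max_pos_in = pick(strengths$in_strength, max),
       max_neg_in = pick(strengths$in_strength, min))
}

#' @export
print.node_strengths <- function(x, digits = 3, ...) {
  cat("Signed directed node strengths (self-connections excluded):\n")
  y <- x
  y$out_strength <- round(y$out_strength, digits)
  y$in_strength <- round(y$in_strength, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
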
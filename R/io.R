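#' Read an undirected PPI network from a two-column edge list
#'
#' Parses a DIP-style tab- or comma-separated edge list of protein-ID
#' pairs into a [`ppi_network`] object. Duplicate edges (in either
#' orientation) are collapsed and self-interactions dropped, the usual
#' cleaning applied to interaction databases before network analysis.
#' Node order is first appearance in the file, and all downstream
#' matrices and score vectors use that order.
#'
#' @param path Path to a text file with two delimited columns of protein
#'   IDs per line. Lines starting with `#` and blank lines are skipped.
#' @param sep Field delimiter. `NULL` (default) auto-detects tab vs
#'   comma; otherwise a single character.
#' @return A `ppi_network` object; see [ppi_network()].
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB", "B\tA", "A\tA", "B\tC"), tf)
#' net <- read_ppi_edgelist(tf)
#' net$n_nodes  # 3
#' net$n_edges  # 2
read_ppi_edgelist <- function(path, sep = NULL) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    stop("empty edge list: ", path, call. = FALSE)
  }
  sep <- sep %||% detect_sep(lines[[1L]])
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", bad[1L], " (expected 2 columns): ",
         lines[bad[1L]], call. = FALSE)
  }
  from <- trimws(vapply(parts, `[[`, "", 1L))
  to <- trimws(vapply(parts, `[[`, "", 2L))
  ppi_network(from, to)
}

#' Construct a PPI network from vectors of interacting protein IDs
#'
#' @param from,to Character vectors of equal length; each position is one
#'   reported interaction. Self-pairs and duplicates are removed.
#' @param nodes Optional character vector fixing the node universe and
#'   order (must contain every interacting protein); lets proteins with
#'   no interactions be retained. Default: first-appearance order of the
#'   interacting proteins.
#' @return An object of class `ppi_network`: a list with `node_ids`
#'   (first-appearance order), `edges` (two-column integer matrix of node
#'   indices, `i < j` per row), `adj` (per-node integer vector of
#'   neighbour indices), `degree`, `n_nodes` and `n_edges`.
#' @export
ppi_network <- function(from, to, nodes = NULL) {
  stopifnot(length(from) == length(to))
  from <- trimws(as.character(from))
  to <- trimws(as.character(to))
  if (any(from == "" | to == "")) {
    stop("empty protein ID in edge list", call. = FALSE)
  }
  # node order: first appearance scanning each line left-to-right
  ids <- unique(as.vector(rbind(from, to)))
  if (!is.null(nodes)) {
    nodes <- trimws(as.character(nodes))
    if (anyDuplicated(nodes)) stop("duplicate node IDs", call. = FALSE)
    missing <- setdiff(ids, nodes)
    if (length(missing) > 0L) {
      stop("edge list mentions proteins outside `nodes`: ",
           paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
    }
    ids <- nodes
  }
  i <- match(from, ids)
  j <- match(to, ids)
  keep <- i != j                       # drop self-interactions
  i <- i[keep]; j <- j[keep]
  lo <- pmin(i, j); hi <- pmax(i, j)
  dup <- duplicated(lo * (length(ids) + 1) + hi)
  lo <- lo[!dup]; hi <- hi[!dup]
  ord <- order(lo, hi)
  edges <- cbind(i = lo[ord], j = hi[ord])
  adj <- adjacency_list(edges, length(ids))
  structure(
    list(
      node_ids = ids,
      edges = edges,
      adj = adj,
      degree = lengths(adj),
      n_nodes = length(ids),
      n_edges = nrow(edges)
    ),
    class = "ppi_network"
  )
}

adjacency_list <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    nb <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
    idx <- as.integer(names(nb))
    adj[idx] <- lapply(nb, function(x) sort(as.integer(x)))
  }
  adj[vapply(adj, is.null, TRUE)] <- list(integer(0))
  adj
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", x$n_nodes, "proteins,", x$n_edges, "interactions\n")
  cat("  mean degree:", format(2 * x$n_edges / max(1L, x$n_nodes), digits = 4),
      "\n")
  invisible(x)
}

#' Dense adjacency matrix of a PPI network
#'
#' @param network A [ppi_network()] object.
#' @return A symmetric 0/1 matrix with protein IDs as dimnames.
#' @export
adjacency_matrix <- function(network) {
  a <- matrix(0, network$n_nodes, network$n_nodes,
              dimnames = list(network$node_ids, network$node_ids))
  if (network$n_edges > 0L) {
    a[network$edges] <- 1
    a[network$edges[, 2:1, drop = FALSE]] <- 1
  }
  a
}

#' Read a time-course expression table aligned to a network
#'
#' First column is the protein ID, remaining `T` columns are numeric
#' expression levels over time points. Proteins in the network without a
#' row are flagged uncovered (expression compendia rarely cover a full
#' interactome); file rows for proteins outside the network are dropped
#' with a message.
#'
#' @param path Delimited text file; a header line is detected and skipped
#'   when its numeric fields fail to parse.
#' @param network A [ppi_network()] giving the node universe and order.
#' @param sep Field delimiter; `NULL` auto-detects tab vs comma.
#' @return An `expression_table`: list with `values` (N x T numeric
#'   matrix, rows in network node order, `NA` rows for uncovered
#'   proteins), `covered` (logical N), `n_timepoints`.
#' @export
read_expression_table <- function(path, network, sep = NULL) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) stop("empty expression table: ", path, call. = FALSE)
  sep <- sep %||% detect_sep(lines[[1L]])
  parts <- strsplit(lines, sep, fixed = TRUE)
  widths <- vapply(parts, length, 1L)
  # header detection: first line whose numeric fields do not parse
  first_vals <- suppressWarnings(as.numeric(parts[[1L]][-1L]))
  if (length(parts) > 1L && anyNA(first_vals)) {
    parts <- parts[-1L]; widths <- widths[-1L]
  }
  if (length(unique(widths)) != 1L) {
    stop("inconsistent column counts in expression table (",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  }
  tp <- widths[[1L]] - 1L
  if (tp < 1L) stop("expression table needs >= 1 numeric column", call. = FALSE)
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[-1L])),
                   numeric(tp)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    stop("non-numeric expression value for protein '", ids[bad], "'",
         call. = FALSE)
  }
  profiles <- stats::setNames(lapply(seq_len(nrow(vals)),
                                     function(r) vals[r, ]), ids)
  expression_table(profiles, network)
}

#' Assemble an expression table from per-protein vectors
#'
#' @param profiles Named list of numeric vectors (one per protein, equal
#'   lengths). Names are protein IDs.
#' @param network A [ppi_network()]; proteins absent from `profiles` are
#'   flagged uncovered.
#' @return An `expression_table`; see [read_expression_table()].
#' @export
expression_table <- function(profiles, network) {
  lens <- unique(lengths(profiles))
  if (length(lens) > 1L) {
    stop("expression vectors have differing lengths: ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  tp <- if (length(lens) == 1L) lens else 0L
  ids <- names(profiles)
  extra <- setdiff(ids, network$node_ids)
  if (length(extra) > 0L) {
    message(length(extra), " expression rows not in the network; ignored")
  }
  values <- matrix(NA_real_, network$n_nodes, max(tp, 1L),
                   dimnames = list(network$node_ids, NULL))
  hit <- intersect(ids, network$node_ids)
  for (id in hit) values[id, ] <- as.numeric(profiles[[id]])
  covered <- stats::setNames(network$node_ids %in% hit, network$node_ids)
  structure(
    list(values = values, covered = covered, n_timepoints = max(tp, 1L)),
    class = "expression_table"
  )
}

#' Read subcellular localization annotations
#'
#' Two delimited columns per line: protein ID, compartment name. A
#' protein's localization set is the union over its lines; duplicated
#' lines are harmless.
#'
#' @param path Delimited text file.
#' @param vocabulary Optional character vector fixing the compartment
#'   vocabulary; defaults to the compartments observed in the file.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return A `localization_table`: list with `sets` (named list of
#'   character vectors) and `vocabulary`.
#' @export
read_localization_table <- function(path, vocabulary = NULL, sep = NULL) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(localization_table(list(), vocabulary %||% character(0)))
  }
  sep <- sep %||% detect_sep(lines[[1L]])
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0L) {
    # strsplit drops trailing empty fields; a line ending in the
    # delimiter is a present-but-empty compartment, not a missing column
    if (endsWith(lines[bad[1L]], sep)) {
      stop("empty compartment field at line ", bad[1L], call. = FALSE)
    }
    stop("malformed localization line ", bad[1L], ": ", lines[bad[1L]],
         call. = FALSE)
  }
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  comp <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(comp == "")) {
    stop("empty compartment field at line ", which(comp == "")[1L],
         call. = FALSE)
  }
  sets <- lapply(split(comp, ids), unique)
  localization_table(sets, vocabulary)
}

#' Assemble a localization table from per-protein compartment sets
#'
#' @param sets Named list of character vectors of compartment names.
#' @param vocabulary Optional explicit compartment vocabulary; every
#'   annotated compartment must belong to it.
#' @return A `localization_table` object.
#' @export
localization_table <- function(sets, vocabulary = NULL) {
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  observed <- sort(unique(unlist(sets, use.names = FALSE))) %||% character(0)
  if (is.null(vocabulary)) {
    vocabulary <- observed
  } else {
    vocabulary <- as.character(vocabulary)
    unknown <- setdiff(observed, vocabulary)
    if (length(unknown) > 0L) {
      stop("compartments outside the vocabulary: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(sets = sets, vocabulary = vocabulary),
            class = "localization_table")
}

#' Read per-protein ortholog counts
#'
#' Accepts two dialects: (a) two columns, protein ID and a nonnegative
#' integer ortholog count; (b) `1 + n_organisms` columns, protein ID
#' followed by one 0/1 presence flag per reference organism, summed to a
#' count. Proteins absent from the file receive count 0 when the table
#' is later aligned to a network.
#'
#' @param path Delimited text file.
#' @param n_organisms Number of reference organisms `|S|`; upper bound on
#'   any count.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return An `orthology_table`: list with `counts` (named integer) and
#'   `n_organisms`.
#' @export
read_orthology_table <- function(path, n_organisms, sep = NULL) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(orthology_table(integer(0), n_organisms))
  }
  sep <- sep %||% detect_sep(lines[[1L]])
  parts <- strsplit(lines, sep, fixed = TRUE)
  widths <- unique(vapply(parts, length, 1L))
  if (length(widths) != 1L) {
    stop("inconsistent column counts in orthology table", call. = FALSE)
  }
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  if (widths == 2L) {
    counts <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    if (anyNA(counts)) stop("non-integer ortholog count", call. = FALSE)
  } else if (widths == n_organisms + 1L) {
    flag_rows <- lapply(parts, function(p) {
      f <- suppressWarnings(as.integer(p[-1L]))
      if (anyNA(f) || any(f < 0L | f > 1L)) {
        stop("orthology flags must be 0/1", call. = FALSE)
      }
      f
    })
    counts <- vapply(flag_rows, sum, 1L)
  } else {
    stop("orthology table must have 2 or 1+n_organisms columns; got ",
         widths, call. = FALSE)
  }
  orthology_table(stats::setNames(counts, ids), n_organisms)
}

#' Assemble an orthology table from named counts
#'
#' @param counts Named nonnegative integer vector of ortholog counts
#'   `I(i)` (number of reference organisms with an ortholog).
#' @param n_organisms Number of reference organisms `|S|`.
#' @return An `orthology_table` object.
#' @export
orthology_table <- function(counts, n_organisms) {
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_organisms <- as.integer(n_organisms)
  if (any(counts < 0L)) stop("negative ortholog count", call. = FALSE)
  if (any(counts > n_organisms)) {
    stop("ortholog count exceeds the number of reference organisms (",
         n_organisms, ")", call. = FALSE)
  }
  structure(list(counts = counts, n_organisms = n_organisms),
            class = "orthology_table")
}

#' Read a known-essential-protein list
#'
#' One protein ID per line; `#` comments and blanks skipped. Used only
#' for evaluation, never by the ranking itself.
#'
#' @param path Text file path.
#' @return Character vector of unique essential-protein IDs.
#' @export
read_essential_list <- function(path) {
  unique(trimws(read_data_lines(path)))
}

#' Write a ranked protein list to a TSV file
#'
#' Columns `rank`, `protein`, `score` with a header line; scores are
#' written with enough digits to round-trip (15 significant digits).
#'
#' @param ranked A data frame as returned by [rank_proteins()] (columns
#'   `rank`, `protein`, `score`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranked, path) {
  stopifnot(is.data.frame(ranked), nrow(ranked) > 0L)
  out <- data.frame(
    rank = ranked$rank,
    protein = ranked$protein,
    score = formatC(ranked$score, digits = 15, format = "g"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a ranking written by [write_ranking()]
#'
#' @param path TSV file with columns `rank`, `protein`, `score`.
#' @return Data frame with the same columns, scores numeric.
#' @export
read_ranking <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "numeric"))
  names(df) <- c("rank", "protein", "score")
  df
}

# -- internal helpers --------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lines
}

detect_sep <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t"
  else if (grepl(",", line, fixed = TRUE)) ","
  else "\t"
}
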
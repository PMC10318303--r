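#' @keywords internal
"_PACKAGE"

# ---- constructors / validators -------------------------------------------

WM_MAXIMA <- c(wm_letter = 48, wm_number = 108, wm_spatial = 30)

#' Validate and type a subject phenotype table
#'
#' Checks the invariants the analysis relies on: unique subject ids, finite
#' numeric ages, non-negative D1-receptor binding potentials, and working
#' memory task scores within their task maxima (letter updating 0--48, number
#' updating 0--108, spatial updating 0--30).
#'
#' @param df Data frame with at least `subject_id` and `age`; recognised
#'   optional columns: `d1dr_bpnd`, `sex` (F/M), `education`, `fd_mean`,
#'   `wm_letter`, `wm_number`, `wm_spatial`.
#' @return The validated data frame (invisibly classed `subject_table`).
#' @export
validate_subject_table <- function(df) {
  req <- c("subject_id", "age")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("subject table is missing required column(s): ",
                         paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  df$age <- as_numeric_col(df$age, "age")
  if (any(!is.finite(df$age))) stop("non-finite or non-numeric age")
  if ("d1dr_bpnd" %in% names(df)) {
    df$d1dr_bpnd <- as_numeric_col(df$d1dr_bpnd, "d1dr_bpnd")
    if (any(df$d1dr_bpnd < 0, na.rm = TRUE)) stop("d1dr_bpnd must be >= 0")
  }
  if ("sex" %in% names(df)) {
    df$sex <- as.character(df$sex)
    bad <- !df$sex %in% c("F", "M") & !is.na(df$sex)
    if (any(bad)) stop("sex must be coded F or M")
  }
  for (col in names(WM_MAXIMA)) {
    if (!col %in% names(df)) next
    df[[col]] <- as_numeric_col(df[[col]], col)
    mx <- WM_MAXIMA[[col]]
    out <- which(df[[col]] < 0 | df[[col]] > mx)
    if (length(out))
      stop(col, " out of range for subject(s) ",
           paste(df$subject_id[out], collapse = ", "),
           ": scores must lie in [0, ", mx, "] (task maximum ", mx, ")")
  }
  class(df) <- unique(c("subject_table", class(df)))
  df
}

as_numeric_col <- function(x, name) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    y <- suppressWarnings(as.numeric(x))
    if (any(is.na(y) & !is.na(x))) stop("column '", name, "' is not numeric")
    return(y)
  }
  as.numeric(x)
}

#' Build a node-to-network partition
#'
#' @param node_ids Character vector of node identifiers (unique, ordered as in
#'   the connectivity matrices).
#' @param network Character/factor vector of network labels, one per node.
#' @return A `network_partition`: list with `node_ids`, `network` (character),
#'   `networks` (ordered unique labels) and `sizes` (named counts).
#' @export
network_partition <- function(node_ids, network) {
  node_ids <- as.character(node_ids)
  network <- as.character(network)
  if (length(node_ids) != length(network))
    stop("node_ids and network must have equal length")
  if (anyDuplicated(node_ids)) stop("duplicate node_id in partition")
  labs <- unique(network)
  if (length(labs) < 2) stop("partition must contain at least 2 networks")
  sizes <- table(factor(network, levels = labs))
  structure(list(node_ids = node_ids, network = network,
                 networks = labs, sizes = c(sizes)),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat("network_partition:", length(x$node_ids), "nodes in",
      length(x$networks), "networks\n")
  print(x$sizes)
  invisible(x)
}

#' Construct a Fisher-z connectivity matrix object
#'
#' Enforces the container invariants: square, symmetric within `tol`, finite
#' entries, and an exactly zero main diagonal (self-connections carry no
#' information and are conventionally zeroed).
#'
#' @param values Square numeric matrix of Fisher-z correlations.
#' @param node_ids Optional node identifiers (defaults to dimnames or
#'   generated labels).
#' @param tol Symmetry tolerance.
#' @param zero_diagonal If `TRUE` (default) a nonzero diagonal is zeroed with
#'   a warning rather than rejected.
#' @return A `connectivity_matrix`: list with `values` and `node_ids`.
#' @export
connectivity_matrix <- function(values, node_ids = NULL, tol = 1e-8,
                                zero_diagonal = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (any(!is.finite(values))) stop("connectivity matrix has non-finite entries")
  if (max(abs(values - t(values))) > tol)
    stop("connectivity matrix asymmetric beyond tolerance ", tol)
  if (any(diag(values) != 0)) {
    if (!zero_diagonal) stop("main diagonal must be zero")
    warning("nonzero main diagonal set to zero")
    diag(values) <- 0
  }
  if (is.null(node_ids)) {
    node_ids <- rownames(values)
    if (is.null(node_ids)) node_ids <- default_node_ids(nrow(values))
  }
  if (length(node_ids) != nrow(values)) stop("node_ids length mismatch")
  dimnames(values) <- list(node_ids, node_ids)
  structure(list(values = values, node_ids = as.character(node_ids)),
            class = "connectivity_matrix")
}

#' Construct a subjects-by-edges data matrix
#'
#' @param values Numeric matrix, one row per subject, columns in the canonical
#'   edge order of [edge_index()].
#' @param n_nodes Node count backing the edge columns.
#' @param subject_ids Subject identifiers matching the rows.
#' @param node_ids Optional node identifiers.
#' @return An `edge_matrix`: list with `values`, `edge_index`, `subject_ids`,
#'   `n_nodes`.
#' @export
edge_matrix <- function(values, n_nodes, subject_ids = NULL, node_ids = NULL) {
  values <- as.matrix(values)
  ne <- n_nodes * (n_nodes - 1) / 2
  if (ncol(values) != ne)
    stop("edge count ", ncol(values), " != n_nodes*(n_nodes-1)/2 = ", ne)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%04d", seq_len(nrow(values)))
  if (length(subject_ids) != nrow(values)) stop("subject_ids length mismatch")
  structure(list(values = values,
                 edge_index = edge_index(n_nodes, node_ids),
                 subject_ids = as.character(subject_ids),
                 n_nodes = as.integer(n_nodes)),
            class = "edge_matrix")
}

#' @export
print.edge_matrix <- function(x, ...) {
  cat("edge_matrix:", nrow(x$values), "subjects x", ncol(x$values),
      "edges (", x$n_nodes, "nodes )\n")
  invisible(x)
}

# ---- readers --------------------------------------------------------------

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl(",", line, fixed = TRUE)) "," else ""
}

#' Read a subject phenotype table from delimited text
#'
#' Comma- or whitespace/tab-delimited text with a header row; the delimiter is
#' auto-detected. Columns `subject_id` and `age` are required; optional
#' phenotypes (`d1dr_bpnd`, `sex`, `education`, `fd_mean`, `wm_letter`,
#' `wm_number`, `wm_spatial`) are validated when present.
#'
#' @param path File path.
#' @return A validated `subject_table` data frame.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_subject_table(df)
}

#' Write a subject table as CSV
#' @param table A `subject_table`.
#' @param path Output file path.
#' @export
write_subject_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a node-to-network partition file
#'
#' Two-column delimited text (`node_id`, `network`), one row per node, with or
#' without a header.
#'
#' @param path File path.
#' @return A `network_partition`.
#' @export
read_partition <- function(path) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), if (sep == ",") "," else "[ \t]+")[[1]]
  header <- any(tolower(first) %in% c("node_id", "node", "network", "network_label"))
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("partition file must have two columns: node_id, network")
  network_partition(df[[1]], df[[2]])
}

#' Write a partition as CSV
#' @param partition A `network_partition`.
#' @param path Output file path.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(data.frame(node_id = partition$node_ids,
                              network = partition$network),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one connectivity matrix from delimited text
#'
#' A square numeric matrix, whitespace- or comma-delimited, with an optional
#' header row of node ids.
#'
#' @param path File path.
#' @param tol Symmetry tolerance.
#' @return A `connectivity_matrix`.
#' @export
read_connectivity_matrix <- function(path, tol = 1e-8) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), if (sep == ",") "," else "[ \t]+")[[1]]
  first <- first[nzchar(first)]
  header <- all(is.na(suppressWarnings(as.numeric(first))))
  m <- as.matrix(utils::read.table(path, header = header, sep = sep))
  node_ids <- if (header) colnames(m) else NULL
  rownames(m) <- NULL
  connectivity_matrix(m, node_ids = node_ids, tol = tol)
}

#' Write a connectivity matrix as delimited text
#' @param m A `connectivity_matrix` or plain symmetric matrix.
#' @param path Output file path.
#' @param digits Significant digits to keep (default full precision).
#' @export
write_connectivity_matrix <- function(m, path, digits = 17) {
  v <- as_conn_values(m)
  utils::write.table(format(v, digits = digits, trim = TRUE, scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and vectorize a stack of per-subject connectivity matrices
#'
#' Reads one square matrix file per subject, validates each against the
#' partition's node count (symmetry within `tol`, finite entries, diagonal
#' zeroed with a warning when nonzero), and stacks the canonical edge vectors
#' into a subjects-by-edges matrix.
#'
#' @param paths Character vector of matrix file paths (one per subject).
#' @param partition A `network_partition` fixing the expected node count/ids.
#' @param subject_ids Optional subject ids (defaults to file basenames).
#' @param tol Symmetry tolerance.
#' @return An `edge_matrix`.
#' @export
load_connectome_stack <- function(paths, partition, subject_ids = NULL,
                                  tol = 1e-8) {
  stopifnot(inherits(partition, "network_partition"))
  n <- length(partition$node_ids)
  rows <- lapply(paths, function(p) {
    cm <- read_connectivity_matrix(p, tol = tol)
    if (nrow(cm$values) != n)
      stop("matrix ", p, " has ", nrow(cm$values),
           " nodes; partition expects ", n)
    vectorize_edges(cm$values, tol = tol)
  })
  if (is.null(subject_ids))
    subject_ids <- sub("\\.[^.]*$", "", basename(paths))
  edge_matrix(do.call(rbind, rows), n_nodes = n, subject_ids = subject_ids,
              node_ids = partition$node_ids)
}
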
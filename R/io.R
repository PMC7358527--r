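#' @importFrom utils read.csv write.csv modifyList head
NULL

# Declared schemas for the five study table kinds. Count-like columns must be
# numeric and non-negative.
.table_schemas <- list(
  enumeration = list(
    columns = c("sample_id", "treatment", "month", "plot",
                "viral_abundance", "bacterial_abundance"),
    counts = c("viral_abundance", "bacterial_abundance")
  ),
  induction = list(
    columns = c("sample_id", "treatment", "month", "plot",
                "v_control", "v_mitc", "b_control", "b_mitc"),
    counts = c("v_control", "v_mitc", "b_control", "b_mitc")
  ),
  peaks = list(
    columns = c("sample_id", "replicate", "size", "height"),
    counts = c("size", "height")
  ),
  bands = list(
    columns = c("label", "treatment", "month", "position"),
    counts = c("position")
  ),
  edaphics = list(
    columns = c("sample_id", "treatment", "month", "plot", "moisture",
                "organic_c", "total_n", "c_n", "p", "ph"),
    counts = c("moisture", "organic_c", "total_n", "c_n", "p", "ph")
  )
)

#' Study table kinds
#'
#' @return Character vector of recognised table kinds.
#' @export
table_kinds <- function() names(.table_schemas)

#' Read and validate a study table
#'
#' Reads one of the five study table kinds (enumeration, induction, peaks,
#' bands, edaphics) from CSV (default) or TSV, validates the header against
#' the declared schema, coerces numeric payload columns and rejects negative
#' counts.
#'
#' @param path Path to a delimited text file with a header row.
#' @param kind One of [table_kinds()].
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return A `data.frame` with attribute `kind`.
#' @export
read_study_table <- function(path, kind, sep = ",") {
  kind <- match.arg(kind, table_kinds())
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  validate_study_table(df, kind)
}

#' Validate an in-memory study table against its schema
#'
#' @param df A data frame.
#' @param kind One of [table_kinds()].
#' @return `df`, with numeric columns coerced and attribute `kind` set.
#' @export
validate_study_table <- function(df, kind) {
  kind <- match.arg(kind, table_kinds())
  sch <- .table_schemas[[kind]]
  missing <- setdiff(sch$columns, names(df))
  if (length(missing) > 0) {
    stop("schema error [", kind, "]: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in sch$counts) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0) {
      stop("parse error [", kind, "]: non-numeric value in column '", col,
           "' at row ", bad[1])
    }
    neg <- which(!is.na(num) & num < 0)
    if (length(neg) > 0) {
      stop("parse error [", kind, "]: negative value in column '", col,
           "' at row ", neg[1])
    }
    df[[col]] <- num
  }
  attr(df, "kind") <- kind
  df
}

#' Write a study table to CSV
#'
#' @param df A validated study table.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(df, path, sep = ",") {
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL

#' Write a UPGMA dendrogram as Newick
#'
#' Branch lengths follow the cophenetic convention in which a leaf under a
#' merge at height h sits at depth h from that node: a two-leaf tree merged at
#' height 3 serialises as `(A:3,B:3);`. Re-reading with [ape::read.tree()]
#' reproduces topology and merge heights.
#'
#' @param tree An `hclust` object (as returned by [upgma()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "hclust")) stop("tree must be an hclust object")
  if (length(tree$labels) < 2) stop("cannot serialise a tree with < 2 leaves")
  t2 <- tree
  # ape::as.phylo.hclust places each node at height/2; double so node depth
  # equals the recorded merge height.
  t2$height <- 2 * t2$height
  ph <- ape::as.phylo(t2)
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Read a Newick dendrogram and recover merge heights
#'
#' @param path Path to a Newick file written by [write_newick()].
#' @return A list with `phylo` (the [ape::read.tree()] object) and
#'   `cophenetic` (leaf-pair merge heights, i.e. half the tree-path distance).
#' @export
read_newick <- function(path) {
  ph <- ape::read.tree(path)
  list(phylo = ph, cophenetic = stats::cophenetic(ph) / 2)
}

# JSON sidecar recording seed and configuration next to an output file.
# File-system locations are excluded so the hash reflects only the
# parameters that determine the output's content.
write_sidecar <- function(path, config, seed) {
  config <- config[setdiff(names(config),
                           c("out", "in", "species", "env", "config"))]
  cfg <- config[order(names(config))]
  sidecar <- list(
    seed = seed,
    config = cfg,
    config_hash = unname(tools::md5sum(
      textConnection_md5(jsonlite::toJSON(cfg, auto_unbox = TRUE))
    ))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

# md5 of a string via a temp file (tools::md5sum is file-based)
textConnection_md5 <- function(x) {
  tf <- tempfile()
  writeLines(as.character(x), tf)
  tf
}
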
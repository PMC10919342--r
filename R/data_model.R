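#' Construct an ASV count table
#'
#' The canonical container for one sequencing pool: a numeric matrix with
#' samples in rows and amplicon sequence variants (ASVs) in columns, tagged
#' with the pool it was derived from (`"DNA"` for 16S genes, `"RNA"` for 16S
#' transcripts).
#'
#' Counts may be non-integer: copy-number correction and rarefaction
#' averaging both produce real-valued tables. Operations that require raw
#' integer counts (e.g. [rarefy_repeated()]) validate integrality themselves.
#'
#' @param counts Numeric matrix, samples x ASVs, with row and column names.
#' @param pool One of `"DNA"` or `"RNA"`.
#' @return A numeric matrix of class `"asv_table"` with a `pool` attribute.
#' @examples
#' m <- matrix(c(5, 2, 0, 0, 7, 1), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("a1", "a2")))
#' asv_table(m, "DNA")
#' @export
asv_table <- function(counts, pool = c("DNA", "RNA")) {
  pool <- match.arg(pool)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  validate_asv_table(counts)
  structure(counts, pool = pool, class = c("asv_table", class(counts)))
}

#' @rdname asv_table
#' @param x Matrix to validate.
#' @export
validate_asv_table <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must have sample (row) and ASV (column) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate ASV ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-finite count at sample '", rownames(x)[bad[1, 1]],
         "', ASV '", colnames(x)[bad[1, 2]], "'")
  invisible(x)
}

#' Pool of an ASV table
#' @param x An `asv_table`.
#' @return `"DNA"` or `"RNA"` (or `NULL` for a bare matrix).
#' @export
table_pool <- function(x) attr(x, "pool")

#' Read a delimited count table
#'
#' Reads a TSV/CSV count table with labelled rows and columns into the
#' canonical samples x ASVs orientation.
#'
#' @param path Path to a delimited text file with a header row and row labels
#'   in the first column.
#' @param pool `"DNA"` or `"RNA"`.
#' @param orientation `"samples_rows"` (default) if samples are the file's
#'   rows, `"samples_cols"` if ASVs are the rows (the file is transposed on
#'   read).
#' @param sep Field separator (default tab).
#' @return An [asv_table()].
#' @export
read_count_table <- function(path, pool = c("DNA", "RNA"),
                             orientation = c("samples_rows", "samples_cols"),
                             sep = "\t") {
  pool <- match.arg(pool)
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, comment.char = "",
                           colClasses = "character")
  m <- matrix(NA_real_, nrow(raw), ncol(raw),
              dimnames = list(rownames(raw), colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("non-numeric count at row '", rownames(raw)[i], "', column '",
           colnames(raw)[j], "' in ", path)
    }
    m[, j] <- v
  }
  if (orientation == "samples_cols") m <- t(m)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative count at row '", rownames(m)[bad[1, 1]], "', column '",
         colnames(m)[bad[1, 2]], "' in ", path)
  asv_table(m, pool)
}

#' Write a count table as delimited text
#'
#' Inverse of [read_count_table()]: samples in rows, ASVs in columns, row
#' labels in the first column under the header `sample_id`.
#'
#' @param x Count matrix (samples x ASVs).
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_count_table <- function(x, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair DNA and RNA tables over a common axis
#'
#' Aligns a DNA and an RNA count table onto identical sample and ASV axes.
#' The ASV axis is the sorted union of both tables' ASVs, zero-filled where a
#' pool lacks an ASV; samples must match as sets and keep the DNA table's
#' order.
#'
#' @param dna,rna [asv_table()] objects with pools `"DNA"` and `"RNA"`.
#' @return A list of class `"paired_asv_table"` with elements `dna` and
#'   `rna`, two matrices with identical dimnames.
#' @export
pair_tables <- function(dna, rna) {
  if (!identical(table_pool(dna), "DNA") || !identical(table_pool(rna), "RNA"))
    stop("pair_tables() expects a DNA table and an RNA table, in that order")
  miss_rna <- setdiff(rownames(dna), rownames(rna))
  miss_dna <- setdiff(rownames(rna), rownames(dna))
  if (length(miss_rna) || length(miss_dna))
    stop("sample sets differ between pools; missing from RNA: {",
         paste(miss_rna, collapse = ", "), "}; missing from DNA: {",
         paste(miss_dna, collapse = ", "), "}")
  asvs <- sort(union(colnames(dna), colnames(rna)))
  samples <- rownames(dna)
  expand <- function(m) {
    out <- matrix(0, length(samples), length(asvs),
                  dimnames = list(samples, asvs))
    out[, colnames(m)] <- m[samples, , drop = FALSE]
    out
  }
  structure(list(dna = expand(dna), rna = expand(rna)),
            class = "paired_asv_table")
}

#' @export
print.paired_asv_table <- function(x, ...) {
  cat("Paired ASV table: ", nrow(x$dna), " samples x ", ncol(x$dna),
      " ASVs (DNA + RNA pools)\n", sep = "")
  invisible(x)
}

#' Read and validate sample metadata
#'
#' Metadata must provide, per sample: station id, depth in metres, a
#' per-station depth index (1 = surface ... 7 = bathypelagic) and an
#' analysis-layer label. Within each station the depth index must strictly
#' increase with depth.
#'
#' @param path Delimited text file with columns `sample_id`, `station`,
#'   `depth_m`, `depth_index`, `layer`.
#' @param sep Field separator (default tab).
#' @return A validated data.frame.
#' @export
read_sample_meta <- function(path, sep = "\t") {
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_meta(meta)
}

#' @rdname read_sample_meta
#' @param meta A metadata data.frame to validate.
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "station", "depth_m", "depth_index", "layer")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  if (!all(meta$depth_index %in% 1:7))
    stop("depth_index must be an integer in 1..7")
  for (st in unique(meta$station)) {
    sub <- meta[meta$station == st, ]
    o <- order(sub$depth_index)
    if (any(diff(sub$depth_m[o]) <= 0))
      stop("depth_index does not strictly increase with depth_m at station ", st)
  }
  meta
}

# every sample of a table must have metadata; returns meta rows in table order
match_meta <- function(x, meta) {
  samples <- rownames(if (inherits(x, "paired_asv_table")) x$dna else x)
  miss <- setdiff(samples, meta$sample_id)
  if (length(miss))
    stop("samples without metadata: ", paste(miss, collapse = ", "))
  meta[match(samples, meta$sample_id), , drop = FALSE]
}

#' Read an ASV taxonomy table
#'
#' Seven-rank taxonomy (domain..genus, species optional) with missing values
#' allowed from any rank downward; assigned ranks must form a contiguous
#' prefix (no genus without family).
#'
#' @param path Delimited text file with a column `asv_id` followed by rank
#'   columns.
#' @param sep Field separator (default tab).
#' @return A data.frame keyed by `asv_id`.
#' @export
read_taxonomy <- function(path, sep = "\t") {
  tax <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  validate_taxonomy(tax)
}

#' @rdname read_taxonomy
#' @param tax A taxonomy data.frame to validate.
#' @export
validate_taxonomy <- function(tax) {
  if (!"asv_id" %in% names(tax)) stop("taxonomy lacks an asv_id column")
  if (anyDuplicated(tax$asv_id)) stop("duplicate asv_id in taxonomy")
  ranks <- setdiff(names(tax), "asv_id")
  if (length(ranks) < 2) stop("taxonomy needs at least two rank columns")
  ass <- !is.na(as.matrix(tax[ranks]))
  # contiguous prefix: once a rank is missing, all deeper ranks are missing
  ok <- apply(ass, 1, function(r) all(diff(as.integer(r)) <= 0))
  if (!all(ok))
    stop("non-contiguous rank assignment for ASV(s): ",
         paste(utils::head(tax$asv_id[!ok], 5), collapse = ", "))
  tax
}

#' Read a 16S copy-number lookup
#'
#' Mean 16S rRNA gene copy number per (rank, taxon name), as produced by
#' rRNA copy-number databases.
#'
#' @param path Delimited text file with columns `rank`, `taxon`,
#'   `copy_number`.
#' @param sep Field separator (default tab).
#' @return A data.frame with positive copy numbers.
#' @export
read_copy_numbers <- function(path, sep = "\t") {
  cn <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("rank", "taxon", "copy_number")
  miss <- setdiff(need, names(cn))
  if (length(miss)) stop("copy-number table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(cn$copy_number) | cn$copy_number <= 0))
    stop("copy numbers must be positive")
  cn
}

#' Read a rooted newick phylogeny
#'
#' Thin wrapper around [ape::read.tree()] adding the validation the
#' phylogenetic-diversity functions rely on: the tree must parse, be rooted,
#' and carry finite non-negative branch lengths.
#'
#' @param path Path to a newick file (or a newick string via `text`).
#' @param text Optional newick string, read instead of `path`.
#' @return An [ape::phylo] object.
#' @export
read_newick_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE),
                                   collapse = "")
  single <- regmatches(text,
                       regexec("^\\s*([^():,;]+):([0-9.eE+-]+)\\s*;\\s*$",
                               text))[[1]]
  if (length(single) == 3) {       # one-tip tree: root -> single leaf
    len <- suppressWarnings(as.numeric(single[3]))
    if (is.na(len) || !is.finite(len) || len < 0)
      stop("malformed newick input")
    tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                           tip.label = single[2], edge.length = len,
                           Nnode = 1L),
                      class = "phylo", order = "cladewise")
    return(tree)
  }
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed newick input")
  if (is.null(tree$edge.length))
    stop("newick tree lacks branch lengths")
  if (any(!is.finite(tree$edge.length) | tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (!ape::is.rooted(tree))
    stop("tree must be rooted")
  tree
}

# detection predicate used throughout: present iff abundance > 0
is_detected <- function(x) x > 0
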
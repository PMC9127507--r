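#' Create a gene set
#'
#' A gene set is a named collection of unique gene identifiers. Identifiers
#' are treated as opaque, case-sensitive strings; no identifier translation
#' is performed.
#'
#' @param name Set name (single string).
#' @param genes Character vector of gene identifiers. Duplicates are removed.
#' @param description Optional free-text description.
#' @return An object of class `gene_set` with fields `name`, `genes`,
#'   `description`.
#' @export
gene_set <- function(name, genes, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- unique(as.character(genes))
  genes <- genes[!is.na(genes) & nzchar(genes)]
  if (length(genes) == 0L) {
    stop("gene set '", name, "' is empty", call. = FALSE)
  }
  structure(
    list(name = name, genes = genes, description = as.character(description)[1L]),
    class = "gene_set"
  )
}

#' @exportS3Method base::print
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Coerce a gene_set or character vector to a plain character vector of genes.
set_genes <- function(x) {
  if (inherits(x, "gene_set")) x$genes else unique(as.character(x))
}

set_name <- function(x, default = "query") {
  if (inherits(x, "gene_set")) x$name else default
}

#' Create a gene set collection
#'
#' @param sets A list of `gene_set` objects (or a named list of character
#'   vectors, which are promoted to gene sets).
#' @param source Free-text provenance label.
#' @return An object of class `gene_set_collection`; essentially an ordered,
#'   uniquely named list of gene sets.
#' @export
gene_set_collection <- function(sets, source = "") {
  if (length(sets) > 0L && !inherits(sets[[1L]], "gene_set")) {
    nm <- names(sets)
    if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
      stop("unnamed sets require gene_set objects", call. = FALSE)
    }
    sets <- lapply(seq_along(sets), function(i) gene_set(nm[i], sets[[i]]))
  }
  nms <- vapply(sets, function(s) s$name, character(1L))
  if (anyDuplicated(nms)) {
    stop("duplicate set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nms
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @exportS3Method base::print
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$genes), integer(1L))
  cat("<gene_set_collection> ", length(x$sets), " sets",
      if (nzchar(x$source)) paste0(" from ", x$source), "\n", sep = "")
  if (length(sizes)) {
    cat("  sizes: min ", min(sizes), ", median ", stats::median(sizes),
        ", max ", max(sizes), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
`[[.gene_set_collection` <- function(x, i) x$sets[[i]]

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(x$sets[i], source = x$source)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene<TAB>gene...`. Duplicate
#' genes within a line are collapsed; empty lines are skipped.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f) | seq_along(f) <= 2L]
    if (length(f) < 3L) {
      stop("GMT parse error at line ", lineno[i],
           ": expected name, description and at least one gene", call. = FALSE)
    }
    sets[[i]] <- gene_set(f[1L], f[-(1:2)], description = f[2L])
  }
  gene_set_collection(sets, source = path)
}

#' Write gene sets in GMT format
#'
#' @param collection A [gene_set_collection()].
#' @param path Output file path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s) {
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain one-gene-per-line query list
#'
#' @param path Path to a text file with one gene identifier per line.
#' @param name Name to give the resulting set (default: file base name).
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  genes <- trimws(readLines(path, warn = FALSE))
  genes <- genes[nzchar(genes)]
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  gene_set(name, genes)
}
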
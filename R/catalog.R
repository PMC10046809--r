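#' Read a gene list file
#'
#' Reads a gene-list file in either of two layouts: a headered TSV/CSV whose
#' first column holds gene symbols (an optional second column is treated as a
#' functional category), or a plain one-symbol-per-line file. Symbols are
#' whitespace-trimmed and de-duplicated preserving first occurrence.
#'
#' @param path Path to the list file. `.csv` is read comma-separated,
#'   anything else tab-separated.
#' @param header Logical or `NA`. `NA` (default) auto-detects: if the file has
#'   more than one column, or its first field is a common header word
#'   (`gene`, `symbol`, `name`), the first record is taken as a header.
#' @return A character vector of unique gene symbols in input order. When a
#'   category column is present it is attached as the `"category"` attribute
#'   (named by gene).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("Actb", "Gapdh", "Actb"), f)
#' suppressWarnings(read_gene_list(f, header = FALSE))
#' @export
read_gene_list <- function(path, header = NA) {
  if (!file.exists(path)) abort(sprintf("gene list file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty gene list")
  fields <- strsplit(lines, sep, fixed = TRUE)
  first <- trimws(fields[[1]][1])
  if (is.na(header)) {
    header <- length(fields[[1]]) > 1 ||
      tolower(first) %in% c("gene", "genes", "symbol", "gene_symbol", "name")
  }
  if (isTRUE(header)) {
    fields <- fields[-1]
    if (length(fields) == 0) abort("empty gene list")
  }
  genes <- trimws(vapply(fields, `[`, character(1), 1))
  category <- vapply(fields, function(f) {
    if (length(f) >= 2) trimws(f[2]) else NA_character_
  }, character(1))
  keep <- !duplicated(genes)
  if (any(!keep)) {
    warn(sprintf(
      "%d duplicate gene name(s) in %s; first occurrence kept (e.g. %s)",
      sum(!keep), basename(path), genes[!keep][1]
    ))
  }
  out <- genes[keep]
  if (any(!is.na(category))) {
    attr(out, "category") <- setNames(category[keep], out)
  }
  out
}

gene_column <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    col <- if ("gene" %in% names(x)) x[["gene"]] else x[[1]]
    return(as.character(col))
  }
  abort("expected a character vector or a data frame with a gene column")
}

#' Names flagged as present in both candidate groups
#'
#' The duplicate rule of [partition_genes()], exposed as a standalone
#' predicate: a name is flagged when it occurs both in the housekeeping
#' candidate set and in the remainder of the universe under the active
#' normalization. Under exact (case-sensitive) matching this set is empty by
#' construction; under case-insensitive matching it catches symbols whose
#' case variants fall on both sides.
#'
#' @param hk_names Housekeeping candidate symbols.
#' @param rest_names The non-housekeeping remainder of the universe.
#' @param case_insensitive Compare case-insensitively?
#' @return Character vector of flagged names (as spelled in the universe).
#' @export
flag_cross_group <- function(hk_names, rest_names, case_insensitive = FALSE) {
  norm <- function(x) if (case_insensitive) toupper(trimws(x)) else trimws(x)
  both <- intersect(norm(hk_names), norm(rest_names))
  c(
    hk_names[norm(hk_names) %in% both],
    rest_names[norm(rest_names) %in% both]
  )
}

#' Expand a housekeeping list with numbered family variants
#'
#' Optional expansion rule: for every listed symbol, universe symbols equal to
#' the listed symbol followed by digits (e.g. `Hoxa` covering `Hoxa1`,
#' `Hoxa13`) are added to the housekeeping candidate set. Off by default in
#' [partition_genes()] because family membership is not a well-defined
#' function of the symbol alone.
#'
#' @param hk_names Listed housekeeping symbols.
#' @param universe All gene symbols.
#' @param case_insensitive Match case-insensitively?
#' @return `hk_names` plus matching variant symbols from `universe`.
#' @export
expand_variants <- function(hk_names, universe, case_insensitive = FALSE) {
  norm <- function(x) if (case_insensitive) toupper(x) else x
  stems <- unique(norm(trimws(hk_names)))
  u <- trimws(universe)
  un <- norm(u)
  hit <- rep(FALSE, length(u))
  for (stem in stems) {
    hit <- hit | grepl(paste0("^", stem, "[0-9]+$"), un)
  }
  unique(c(trimws(hk_names), u[hit]))
}

#' Partition a gene universe into housekeeping and integrative groups
#'
#' Builds the HG/IntG catalogue: genes named in the housekeeping list are
#' labelled `HG`, all remaining genes `IntG`, and any name the cross-group
#' duplicate rule flags (see [flag_cross_group()]) is removed from both
#' groups. Matching is exact after whitespace trimming by default;
#' case-insensitive matching and numbered-variant expansion are optional.
#'
#' @param all_genes The gene universe: a character vector or a data frame
#'   whose `gene` (or first) column holds symbols.
#' @param hk_genes Housekeeping candidate symbols (same forms accepted).
#' @param case_insensitive Match symbols case-insensitively?
#' @param expand_variants Apply the numbered-variant expansion of
#'   [expand_variants()] to `hk_genes` before matching?
#' @param flagged Optional explicit character vector of names to remove from
#'   both groups; `NULL` (default) computes it with [flag_cross_group()].
#' @return A `gene_catalog`: a tibble with columns `gene` and `group`
#'   (`"HG"`/`"IntG"`), one row per non-removed gene, with attributes
#'   `removed` (flagged names), `unmatched` (housekeeping names absent from
#'   the universe) and `counts` (named vector `total`, `n_hg`, `n_intg`,
#'   `n_removed`).
#' @examples
#' partition_genes(c("A", "B", "C", "D"), c("A", "B"))
#' @export
partition_genes <- function(all_genes, hk_genes,
                            case_insensitive = FALSE,
                            expand_variants = FALSE,
                            flagged = NULL) {
  universe <- unique(trimws(gene_column(all_genes)))
  if (length(universe) == 0) abort("gene universe is empty")
  hk <- unique(trimws(gene_column(hk_genes)))
  if (expand_variants) {
    hk <- expand_variants(hk, universe, case_insensitive = case_insensitive)
  }

  norm <- function(x) if (case_insensitive) toupper(x) else x
  unmatched <- hk[!norm(hk) %in% norm(universe)]
  is_hg <- norm(universe) %in% norm(hk)

  if (is.null(flagged)) {
    # candidate groups for the duplicate rule: exact housekeeping matches
    # vs the exact remainder; under the active normalization a symbol
    # spelled into both sides is flagged (empty by construction when the
    # normalization is exact matching)
    exact_hg <- universe %in% hk
    flagged <- flag_cross_group(universe[exact_hg], universe[!exact_hg],
      case_insensitive = case_insensitive
    )
  }
  flagged <- unique(trimws(flagged))
  removed <- universe[norm(universe) %in% norm(flagged)]

  keep <- !universe %in% removed
  entries <- tibble::tibble(
    gene = universe[keep],
    group = ifelse(is_hg[keep], "HG", "IntG")
  )
  counts <- c(
    total = length(universe),
    n_hg = sum(entries$group == "HG"),
    n_intg = sum(entries$group == "IntG"),
    n_removed = length(removed)
  )
  structure(entries,
    removed = removed,
    unmatched = unmatched,
    counts = counts,
    class = c("gene_catalog", class(entries))
  )
}

#' @export
print.gene_catalog <- function(x, ...) {
  cts <- attr(x, "counts")
  cat(sprintf(
    "<gene_catalog> %d genes: %d HG, %d IntG, %d removed\n",
    cts[["total"]], cts[["n_hg"]], cts[["n_intg"]], cts[["n_removed"]]
  ))
  if (length(attr(x, "unmatched")) > 0) {
    cat(sprintf(
      "  %d housekeeping name(s) not in universe (e.g. %s)\n",
      length(attr(x, "unmatched")), attr(x, "unmatched")[1]
    ))
  }
  NextMethod()
}

#' @export
glance.gene_catalog <- function(x, ...) {
  cts <- attr(x, "counts")
  tibble::tibble(
    total = cts[["total"]], n_hg = cts[["n_hg"]],
    n_intg = cts[["n_intg"]], n_removed = cts[["n_removed"]],
    n_unmatched = length(attr(x, "unmatched"))
  )
}

catalog_group <- function(catalog, group) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (!group %in% c("HG", "IntG")) abort("group must be 'HG' or 'IntG'")
  catalog$gene[catalog$group == group]
}

#' Reconciliation record of a catalogue build
#'
#' @param catalog A `gene_catalog`.
#' @return A list with `counts`, `removed` and `unmatched`, suitable for
#'   serialization as JSON.
#' @export
catalog_report <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  list(
    counts = as.list(attr(catalog, "counts")),
    removed = attr(catalog, "removed"),
    unmatched = attr(catalog, "unmatched")
  )
}

#' Write a gene catalogue as TSV
#'
#' @param catalog A `gene_catalog`.
#' @param path Output TSV path (columns `gene`, `group`).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(tibble::as_tibble(catalog), path)
  invisible(path)
}

normalize_symbol <- function(x) {
  # repairs whitespace inside a symbol ("GDF 10" -> "GDF10")
  gsub("[[:space:]]+", "", trimws(x))
}

#' Construct a named gene block resolved against a catalogue
#'
#' @param genes Block member symbols (character vector or data frame).
#' @param catalog A `gene_catalog` to resolve against.
#' @param name Block label (e.g. `"repair"`, `"block_I"`).
#' @param case_insensitive Resolve case-insensitively?
#' @return A `gene_block`: a tibble with columns `gene` and `group` for the
#'   resolved members, with attributes `name`, `unresolved` (symbols absent
#'   from the catalogue) and `size`.
#' @export
gene_block <- function(genes, catalog, name, case_insensitive = FALSE) {
  stopifnot(inherits(catalog, "gene_catalog"))
  symbols <- unique(normalize_symbol(gene_column(genes)))
  symbols <- symbols[nzchar(symbols)]
  norm <- function(x) if (case_insensitive) toupper(x) else x
  idx <- match(norm(symbols), norm(catalog$gene))
  unresolved <- symbols[is.na(idx)]
  resolved <- catalog[idx[!is.na(idx)], , drop = FALSE]
  if (nrow(resolved) == 0) {
    abort(sprintf("gene block '%s': no member resolves against the catalogue", name))
  }
  if (length(unresolved) > 0) {
    inform(sprintf(
      "gene block '%s': %d name(s) not in catalogue: %s",
      name, length(unresolved), paste(unresolved, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(resolved)
  structure(out,
    name = name,
    unresolved = unresolved,
    size = nrow(out),
    class = c("gene_block", class(out))
  )
}

#' Read a gene block definition file
#'
#' Reads a block file (same layouts as [read_gene_list()]), repairs
#' whitespace-damaged symbols (`"GDF 10"` becomes `"GDF10"`), and resolves
#' the members against a catalogue via [gene_block()].
#'
#' @inheritParams gene_block
#' @param path Path to the block definition file.
#' @param name Block label; defaults to the file name without extension.
#' @return A `gene_block`.
#' @export
read_gene_block <- function(path, catalog, name = NULL,
                            case_insensitive = FALSE) {
  symbols <- suppressWarnings(read_gene_list(path))
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  gene_block(symbols, catalog, name, case_insensitive = case_insensitive)
}

#' @export
print.gene_block <- function(x, ...) {
  cat(sprintf(
    "<gene_block> '%s': %d gene(s)%s\n",
    attr(x, "name"), attr(x, "size"),
    if (length(attr(x, "unresolved")) > 0) {
      sprintf(", %d unresolved", length(attr(x, "unresolved")))
    } else ""
  ))
  NextMethod()
}
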
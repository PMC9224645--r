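#' Load phenotype-to-gene sets from a genes_to_phenotype-style table
#'
#' Reads a TSV with (at least) columns `gene_symbol`, `hpo_id`, `hpo_name`
#' and builds a flat catalog of phenotype terms, each carrying its
#' deduplicated gene set. No ontology reasoning is performed: terms are used
#' purely as named gene groups.
#'
#' @param path Path to the TSV (header row required).
#' @return A `gv_phenocat` with components `terms` (data.frame: `hpo_id`,
#'   `hpo_name`, `n_genes`) and `gene_map` (named list: term id -> character
#'   vector of gene symbols).
#' @export
load_hpo_sets <- function(path) {
  if (!file.exists(path)) stop("phenotype table not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  required <- c("gene_symbol", "hpo_id", "hpo_name")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("phenotype table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[nzchar(df$hpo_id) & nzchar(df$gene_symbol), , drop = FALSE]
  gene_map <- lapply(split(df$gene_symbol, df$hpo_id),
                     function(g) sort(unique(g)))
  name_of <- vapply(split(df$hpo_name, df$hpo_id), function(n) n[1], "")
  ids <- sort(names(gene_map))
  terms <- data.frame(hpo_id = ids,
                      hpo_name = unname(name_of[ids]),
                      n_genes = vapply(gene_map[ids], length, 0L),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, gene_map = gene_map[ids]),
            class = "gv_phenocat")
}

#' @export
print.gv_phenocat <- function(x, ...) {
  cat(sprintf("<gv_phenocat> %d phenotype terms, %d distinct genes\n",
              nrow(x$terms), length(unique(unlist(x$gene_map)))))
  invisible(x)
}

#' Gene set registered under a phenotype term
#'
#' @param catalog A `gv_phenocat`.
#' @param term_id Term accession (e.g. `"HP:0000001"`).
#' @return List with `label` (term name) and `symbols` (character vector).
#' @export
gene_set_for_term <- function(catalog, term_id) {
  stopifnot(inherits(catalog, "gv_phenocat"))
  i <- match(term_id, catalog$terms$hpo_id)
  if (is.na(i)) {
    near <- utils::head(
      catalog$terms$hpo_id[order(utils::adist(term_id,
                                              catalog$terms$hpo_id))], 3L)
    stop(sprintf("unknown phenotype term '%s'; nearest known terms: %s",
                 term_id, paste(near, collapse = ", ")), call. = FALSE)
  }
  list(label = catalog$terms$hpo_name[i],
       symbols = catalog$gene_map[[term_id]])
}

#' Resolve gene symbols against a gene-model index
#'
#' Case-insensitive lookup that partitions the input into resolved and
#' unresolved symbols, preserving input order. Unknown symbols are reported,
#' not fatal.
#'
#' @param symbols Character vector of gene symbols.
#' @param index A `gv_genemodel`.
#' @return List with `resolved` (canonical symbols as spelled in the index)
#'   and `unresolved` (input spellings with no match).
#' @export
resolve_symbols <- function(symbols, index) {
  stopifnot(inherits(index, "gv_genemodel"))
  if (length(symbols) == 0L) {
    return(list(resolved = character(0), unresolved = character(0)))
  }
  canon <- index$genes$gene
  i <- match(toupper(symbols), toupper(canon))
  list(resolved = canon[i[!is.na(i)]],
       unresolved = symbols[is.na(i)])
}

#' Read a plain gene-list file
#'
#' One symbol per line; blank lines and `#` comments ignored. This is the
#' "user-defined gene list" entry path, as an alternative to selecting a
#' phenotype term.
#'
#' @param path Path to the text file.
#' @return Character vector of symbols (deduplicated, order preserved).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path,
                               call. = FALSE)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
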
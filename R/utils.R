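# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

geomean <- function(x) exp(mean(log(x)))

# mouse -> human symbol mapping: uppercase 1:1 unless an explicit two-column
# ortholog table (mouse, human) is supplied
human_symbols <- function(genes, gene_map = NULL) {
  if (is.null(gene_map)) return(toupper(genes))
  if (!all(c("mouse", "human") %in% names(gene_map)))
    stop("`gene_map` must have columns 'mouse' and 'human'", call. = FALSE)
  idx <- match(genes, gene_map$mouse)
  out <- ifelse(is.na(idx), toupper(genes), gene_map$human[idx])
  as.character(out)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stop_bad_arg <- function(name, msg) {
  stop(sprintf("invalid `%s`: %s", name, msg), call. = FALSE)
}
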
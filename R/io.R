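# Plain-text readers and writers for every pipeline format. All writers
# round-trip bit-exactly with the corresponding readers.

#' Write a count matrix and its sample table
#'
#' Counts TSV: first column `gene`, second `housekeeping` (TRUE/FALSE),
#' then one column per sample. Samples TSV: `sample`, `sex`, `diet`,
#' `genotype`, `lane`, `site`.
#'
#' @param study List with `counts` (a [count_matrix()]) and `samples`.
#' @param counts_file,samples_file Output paths.
#' @export
write_study <- function(study, counts_file, samples_file) {
  cm <- study$counts
  df <- data.frame(gene = rownames(cm$counts),
                   housekeeping = rownames(cm$counts) %in% cm$housekeeping,
                   cm$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, samples_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_file, samples_file))
}

#' Read a count matrix and its sample table
#'
#' @param counts_file,samples_file Paths written by [write_study()].
#' @return List with `counts` (a [count_matrix()]) and `samples`.
#' @export
read_study <- function(counts_file, samples_file) {
  df <- utils::read.delim(counts_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "housekeeping") %in% names(df)))
    stop("counts file must have 'gene' and 'housekeeping' columns",
         call. = FALSE)
  samples <- utils::read.delim(samples_file, colClasses = "character")
  req <- c("sample", "sex", "diet", "genotype", "lane")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("samples file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("gene", "housekeeping")),
                    drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  if (!all(samples$sample %in% colnames(m)))
    stop("samples file lists sample(s) absent from the counts file",
         call. = FALSE)
  m <- m[, samples$sample, drop = FALSE]
  cm <- count_matrix(m, stats::setNames(samples$lane, samples$sample),
                     df$gene[df$housekeeping])
  list(counts = cm, samples = samples)
}

#' Write / read a module (or subtype) reference table
#'
#' TSV columns: `module`, `cluster`, `region`, `gene`, `log2fc`.
#'
#' @param reference Reference data frame.
#' @param file Path.
#' @export
write_module_reference <- function(reference, file) {
  utils::write.table(reference, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_module_reference
#' @export
read_module_reference <- function(file) {
  ref <- utils::read.delim(file, stringsAsFactors = FALSE)
  req <- c("module", "cluster", "region", "gene", "log2fc")
  miss <- setdiff(req, names(ref))
  if (length(miss))
    stop("module reference missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ref
}

#' Write / read a volume-of-interest uptake table
#'
#' CSV columns: `subject`, `sex`, `diet`, `genotype`, `region`, `side`,
#' `uptake`.
#'
#' @param voi VOI data frame.
#' @param file Path.
#' @export
write_voi <- function(voi, file) {
  utils::write.csv(voi, file, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_voi
#' @export
read_voi <- function(file) {
  voi <- utils::read.csv(file, colClasses = c(
    subject = "character", sex = "character", diet = "character",
    genotype = "character", region = "character", side = "character"))
  req <- c("subject", "region", "side", "uptake")
  miss <- setdiff(req, names(voi))
  if (length(miss))
    stop("VOI table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  voi
}

#' Write / read a cytokine measurement table
#'
#' CSV columns: `subject`, `sex`, `diet`, `genotype`, `analyte`, `value`,
#' `below_llod`, `llod`.
#'
#' @param tbl Measurement data frame.
#' @param file Path.
#' @export
write_cytokines <- function(tbl, file) {
  utils::write.csv(tbl, file, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cytokines
#' @export
read_cytokines <- function(file) {
  tbl <- utils::read.csv(file, colClasses = c(
    subject = "character", sex = "character", diet = "character",
    genotype = "character", analyte = "character"))
  req <- c("analyte", "value", "below_llod", "llod")
  miss <- setdiff(req, names(tbl))
  if (length(miss))
    stop("cytokine table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tbl$below_llod <- as.logical(tbl$below_llod)
  tbl
}

#' Write an effect table as TSV
#'
#' @param effects An `effect_table`.
#' @param file Path.
#' @export
write_effect_table <- function(effects, file) {
  utils::write.table(effects, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a correlation grid (long and matrix form)
#'
#' @param grid A `correlation_grid`.
#' @param file Long-form TSV path; the matrix form (Pearson r) is written
#'   next to it with suffix `.matrix.tsv`.
#' @export
write_grid <- function(grid, file) {
  utils::write.table(grid, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m <- grid_matrix(grid, "r")
  mfile <- sub("\\.tsv$", ".matrix.tsv", file)
  if (identical(mfile, file)) mfile <- paste0(file, ".matrix.tsv")
  utils::write.table(data.frame(term = rownames(m), m, check.names = FALSE),
                     mfile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(file, mfile))
}
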
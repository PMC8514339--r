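#' Variant classes excluded from the nonsynonymous mutation count
#'
#' Silent, intronic, UTR, RNA and lincRNA records are dropped by default so
#' that per-gene counts reflect nonsynonymous coding mutations.
#' @export
default_excluded_classes <- c("Silent", "Intron", "3'UTR", "5'UTR",
                              "RNA", "lincRNA")

#' Load somatic mutations as a sample x gene count matrix
#'
#' Accepts either a MAF-like tab-separated file (columns `Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification`; gzip accepted) or an
#' already aggregated gene x sample numeric matrix (CSV/TSV, genes as rows,
#' header row of sample IDs). MAF records whose class is in
#' `excluded_classes` are dropped before counting; unknown classification
#' strings are retained with a warning (fail-open on annotation dialects).
#'
#' @param source File path, or a data frame in either dialect.
#' @param excluded_classes Character vector of `Variant_Classification`
#'   values to drop (default [default_excluded_classes]).
#' @return Integer matrix samples x genes of retained mutation counts,
#'   with class `gene_mutation_matrix`.
#' @export
load_mutations <- function(source, excluded_classes = default_excluded_classes) {
  known_classes <- c(excluded_classes, "Missense_Mutation", "Nonsense_Mutation",
                     "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins",
                     "In_Frame_Del", "Splice_Site", "Translation_Start_Site",
                     "Nonstop_Mutation", "De_novo_Start_InFrame",
                     "De_novo_Start_OutOfFrame", "Start_Codon_SNP",
                     "Start_Codon_Del", "Start_Codon_Ins", "Stop_Codon_Del",
                     "Stop_Codon_Ins", "Missense", "Nonsense", "Indel")
  df <- NULL
  if (is.character(source)) {
    if (!file.exists(source)) stop("mutation file not found: ", source)
    head1 <- readLines(gzfile(source), n = 1)
    if (grepl("Hugo_Symbol", head1)) {
      df <- utils::read.delim(gzfile(source), stringsAsFactors = FALSE,
                              check.names = FALSE, comment.char = "#")
    } else {
      mat <- read_gene_by_sample(source)
      return(matrix_to_mutation(mat))
    }
  } else {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
    if (!"Hugo_Symbol" %in% names(df)) {
      return(matrix_to_mutation(as.matrix(df)))
    }
  }
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col) > 0) {
    stop("MAF input is missing required column(s): ",
         paste(missing_col, collapse = ", "))
  }
  if (nrow(df) == 0) {
    m <- matrix(0L, 0, 0)
    class(m) <- c("gene_mutation_matrix", class(m))
    return(m)
  }
  unknown <- setdiff(unique(df$Variant_Classification), known_classes)
  if (length(unknown) > 0) {
    warning("unknown Variant_Classification value(s) retained: ",
            paste(unknown, collapse = ", "))
  }
  # profiled samples stay even when all their records are filtered out;
  # genes are kept only when seen in a retained record
  samples <- sort(unique(as.character(df$Tumor_Sample_Barcode)))
  keep <- !(df$Variant_Classification %in% excluded_classes)
  df <- df[keep, , drop = FALSE]
  genes <- sort(unique(normalize_gene_symbols(df$Hugo_Symbol)))
  counts <- matrix(0L, nrow = length(samples), ncol = length(genes),
                   dimnames = list(samples, genes))
  if (nrow(df) > 0) {
    tab <- table(factor(df$Tumor_Sample_Barcode, levels = samples),
                 factor(normalize_gene_symbols(df$Hugo_Symbol), levels = genes))
    counts[] <- as.integer(tab)
  }
  class(counts) <- c("gene_mutation_matrix", class(counts))
  counts
}

source_field <- function(df, col) df[[col]]

matrix_to_mutation <- function(mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (any(is.na(mat))) stop("mutation matrix contains missing values")
  if (any(mat < 0)) stop("mutation matrix contains negative counts")
  # input dialect is genes x samples; internal layout is samples x genes
  m <- t(mat)
  rownames(m) <- colnames(mat)
  colnames(m) <- normalize_gene_symbols(rownames(mat))
  m <- m[sort(rownames(m)), sort(colnames(m)), drop = FALSE]
  storage.mode(m) <- "integer"
  class(m) <- c("gene_mutation_matrix", class(m))
  m
}

read_gene_by_sample <- function(path) {
  sep <- if (grepl("\\.tsv(\\.gz)?$|\\.txt(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Load gene-level thresholded copy-number calls
#'
#' Reads a genes x samples matrix of GISTIC-style integer calls in
#' \[-2, 2\] and derives the binary indicators used by the model: only high
#' (+2) gains count as amplification and only deep (-2) deletions count as
#' deletion; single-copy events (+1/-1) map to neither.
#'
#' @param source CSV/TSV path (genes as rows, sample IDs as header) or a
#'   gene x sample matrix/data frame.
#' @return List of class `copy_number_calls` with samples x genes integer
#'   matrices `calls`, `amp`, `del`.
#' @export
load_cnv <- function(source) {
  mat <- if (is.character(source)) read_gene_by_sample(source) else {
    m <- as.matrix(source)
    m
  }
  storage.mode(mat) <- "double"
  if (any(is.na(mat))) stop("copy-number matrix contains missing values")
  bad <- which(!array(mat %in% (-2:2), dim(mat)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("copy-number call outside [-2, 2] at gene '%s', sample '%s'",
                 rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  calls <- t(mat)
  rownames(calls) <- colnames(mat)
  colnames(calls) <- normalize_gene_symbols(rownames(mat))
  calls <- calls[sort(rownames(calls)), sort(colnames(calls)), drop = FALSE]
  storage.mode(calls) <- "integer"
  structure(list(calls = calls,
                 amp = (calls == 2L) * 1L,
                 del = (calls == -2L) * 1L),
            class = "copy_number_calls")
}

#' Load sample labels (0 = primary, 1 = metastatic/CRPC)
#'
#' @param source CSV path or data frame with columns `sample_id` and
#'   `response` (0/1).
#' @return Named integer vector of labels keyed by sample id.
#' @export
load_labels <- function(source) {
  df <- if (is.character(source)) {
    utils::read.csv(source, stringsAsFactors = FALSE)
  } else as.data.frame(source)
  if (!all(c("sample_id", "response") %in% names(df))) {
    stop("labels input needs columns sample_id and response")
  }
  y <- as.integer(df$response)
  if (any(!y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in labels")
  stats::setNames(y, as.character(df$sample_id))
}

#' Assemble the samples x genes x 3 profile tensor
#'
#' Aligns mutation counts and copy-number indicators to the gene layer of a
#' compiled network. Samples are the sorted intersection of the two sources;
#' genes follow the network's gene-layer order, zero-filled where a source
#' lacks the gene. Channels are (mutation, amplification, deletion).
#'
#' @param mut A `gene_mutation_matrix` from [load_mutations()].
#' @param cnv A `copy_number_calls` from [load_cnv()].
#' @param net A `layered_network`.
#' @param binarize_mutations If TRUE (default) the mutation channel is the
#'   0/1 presence of any retained mutation; otherwise raw counts.
#' @return 3-d array samples x genes x 3 (dimnames set, third dim
#'   `mut`/`amp`/`del`), class `profile_tensor`.
#' @export
assemble_profiles <- function(mut, cnv, net, binarize_mutations = TRUE) {
  genes <- net$layers$genes
  if (length(genes) == 0) stop("network has an empty gene layer")
  samples <- sort(intersect(rownames(mut), rownames(cnv$calls)))
  if (length(samples) == 0) stop("no samples shared between mutation and copy-number sources")
  pick <- function(m) {
    out <- matrix(0, nrow = length(samples), ncol = length(genes),
                  dimnames = list(samples, genes))
    common <- intersect(colnames(m), genes)
    if (length(common) > 0) out[, common] <- m[samples, common]
    out
  }
  mutm <- pick(unclass(mut))
  if (binarize_mutations) mutm <- (mutm > 0) * 1
  x <- array(0, dim = c(length(samples), length(genes), 3),
             dimnames = list(samples, genes, c("mut", "amp", "del")))
  x[, , "mut"] <- mutm
  x[, , "amp"] <- pick(cnv$amp)
  x[, , "del"] <- pick(cnv$del)
  structure(x, class = c("profile_tensor", "array"))
}

#' Flatten a profile tensor into the model input matrix
#'
#' Columns follow the network feature-layer order: for each gene (in gene
#' layer order) its mutation, amplification and deletion features.
#'
#' @param tensor A `profile_tensor`.
#' @return Numeric matrix samples x (3 * genes) with feature column names.
#' @export
as_input_matrix <- function(tensor) {
  g <- dim(tensor)[2]
  n <- dim(tensor)[1]
  out <- matrix(0, nrow = n, ncol = 3 * g)
  idx <- rep(seq_len(g), each = 3)
  ch <- rep(1:3, g)
  for (k in 1:3) out[, ch == k] <- tensor[, , k]
  genes <- dimnames(tensor)[[2]]
  colnames(out) <- as.vector(t(outer(genes, c("_mut", "_amp", "_del"), paste0)))
  rownames(out) <- dimnames(tensor)[[1]]
  out
}

#' Write a profile tensor to its flat-file layout
#'
#' Emits `mutation.csv`, `amplification.csv`, `deletion.csv` (genes as rows,
#' samples as columns) into `dir`; [read_profiles()] restores the tensor
#' exactly.
#' @param tensor A `profile_tensor`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_profiles <- function(tensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in c("mut", "amp", "del")) {
    fn <- c(mut = "mutation.csv", amp = "amplification.csv",
            del = "deletion.csv")[[ch]]
    utils::write.csv(t(tensor[, , ch]), file.path(dir, fn))
  }
  invisible(dir)
}

#' Read a profile tensor written by [write_profiles()]
#' @param dir Directory containing the three channel CSVs.
#' @return A `profile_tensor`.
#' @export
read_profiles <- function(dir) {
  rd <- function(fn) {
    m <- utils::read.csv(file.path(dir, fn), row.names = 1, check.names = FALSE)
    t(as.matrix(m))
  }
  mut <- rd("mutation.csv")
  amp <- rd("amplification.csv")
  del <- rd("deletion.csv")
  x <- array(0, dim = c(nrow(mut), ncol(mut), 3),
             dimnames = list(rownames(mut), colnames(mut),
                             c("mut", "amp", "del")))
  x[, , "mut"] <- mut
  x[, , "amp"] <- amp
  x[, , "del"] <- del
  structure(x, class = c("profile_tensor", "array"))
}
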
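#' Load a two-group expression matrix
#'
#' Reads a tab-delimited matrix in the style of a GEO series-matrix table:
#' a header row of sample identifiers and one row per gene/probe, first
#' column the identifier.  Series-matrix values are assumed to already be
#' log2 scale unless \code{apply_log2} is set.
#'
#' Every sample column must be assigned to exactly one of the two groups;
#' unassigned or doubly assigned samples are an error.
#'
#' @param path Path to the tab-delimited file.
#' @param case Character vector of sample ids in the case group (e.g.
#'   glioblastoma / glioma stem cells).
#' @param control Character vector of sample ids in the control group (e.g.
#'   non-tumor brain / neural stem cells).
#' @param apply_log2 If TRUE, values are log2-transformed after reading;
#'   non-positive raw values are then an error.
#' @return Object of class \code{"expression_matrix"}: list with
#'   \code{values} (genes x samples numeric matrix, log2 scale),
#'   \code{genes}, \code{samples} and \code{groups} (factor with levels
#'   \code{control}, \code{case}).
#' @export
read_expression <- function(path, case, control, apply_log2 = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("expression file needs an id column and >= 1 sample")
  genes <- as.character(d[[1]])
  vals <- d[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    failed <- is.na(v) & !is.na(vals[[j]])
    if (any(failed)) {
      bad <- which(failed)[1]
      stop("non-numeric expression value at row '", genes[bad],
           "', column '", names(vals)[j], "'")
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  expression_matrix(m, case = case, control = control,
                    apply_log2 = apply_log2)
}

#' Construct an expression matrix object from a numeric matrix
#'
#' @param values Genes x samples numeric matrix (rownames = gene/probe ids,
#'   colnames = sample ids).
#' @inheritParams read_expression
#' @return An \code{"expression_matrix"} object (see
#'   \code{\link{read_expression}}).
#' @export
expression_matrix <- function(values, case, control, apply_log2 = FALSE) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("the expression matrix needs gene rownames and sample colnames")
  samples <- colnames(values)
  missing <- setdiff(samples, c(case, control))
  if (length(missing))
    stop("sample(s) not assigned to a group: ", paste(missing, collapse = ", "))
  dup <- intersect(case, control)
  if (length(dup))
    stop("sample(s) assigned to both groups: ", paste(dup, collapse = ", "))
  absent <- setdiff(c(case, control), samples)
  if (length(absent))
    stop("labelled sample(s) absent from the matrix: ",
         paste(absent, collapse = ", "))
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (apply_log2) {
    if (any(values <= 0))
      stop("log2 transform requested but non-positive values present")
    values <- log2(values)
  }
  groups <- factor(ifelse(samples %in% case, "case", "control"),
                   levels = c("control", "case"))
  structure(list(values = values, genes = rownames(values),
                 samples = samples, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", length(x$genes), "genes x",
      length(x$samples), "samples (",
      sum(x$groups == "control"), "control,",
      sum(x$groups == "case"), "case )\n")
  invisible(x)
}

#' Two-group log2 fold change of one gene
#'
#' log2FC = mean(case) - mean(control) of the log2 expression values, with a
#' p-value from the Welch t test (no equal-variance assumption).  When
#' several probes map to the gene, the default rule keeps the probe with the
#' highest mean expression; \code{probe_rule = "average"} averages the
#' probes per sample instead.
#'
#' @param m An \code{"expression_matrix"}.
#' @param gene Gene/probe identifier (matched against rownames; multiple
#'   matching rows are treated as probes of the gene).
#' @param probe_rule Aggregation over multiple probes: \code{"max-mean"}
#'   (default) or \code{"average"}.
#' @return List with \code{log2fc} and \code{p}.
#' @examples
#' v <- rbind(IDO1 = c(3, 3, 6, 7, 5))
#' colnames(v) <- paste0("s", 1:5)
#' m <- expression_matrix(v, case = c("s3", "s4", "s5"),
#'                        control = c("s1", "s2"))
#' gene_log2fc(m, "IDO1")
#' @export
gene_log2fc <- function(m, gene, probe_rule = c("max-mean", "average")) {
  if (!inherits(m, "expression_matrix"))
    stop("'m' must be an expression_matrix")
  probe_rule <- match.arg(probe_rule)
  rows <- which(m$genes == gene)
  if (!length(rows)) stop("gene '", gene, "' not found")
  v <- m$values[rows, , drop = FALSE]
  x <- if (nrow(v) == 1) {
    v[1, ]
  } else if (probe_rule == "max-mean") {
    v[which.max(rowMeans(v)), ]
  } else {
    colMeans(v)
  }
  case <- x[m$groups == "case"]
  ctrl <- x[m$groups == "control"]
  if (length(case) < 2 || length(ctrl) < 2)
    stop("both groups need n >= 2")
  wt <- welch_t(case, ctrl)
  list(log2fc = mean(case) - mean(ctrl), p = wt$p)
}

#' Significance rule: fold change > 2 and p < 0.05
#'
#' The study's criterion for a differentially expressed gene: absolute fold
#' change above 2 (|log2FC| > 1, two-sided) together with p < 0.05.
#'
#' @param log2fc Log2 fold change.
#' @param p P-value in [0, 1].
#' @return Logical.
#' @examples
#' flag_significant(2.73, 0.005)  # TRUE
#' flag_significant(0.88, 0.024)  # FALSE: fold change > 2 not reached
#' @export
flag_significant <- function(log2fc, p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  abs(log2fc) > 1 & p < 0.05
}
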
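#' Read a delimited expression matrix
#'
#' Genes in rows, first column gene names, header row of cell/time labels.
#' The delimiter is taken from the file extension (`.csv` = comma,
#' otherwise tab). `transpose = TRUE` accepts the cells-in-rows dialect.
#'
#' @param path input file
#' @param transpose input has cells in rows and genes in columns
#' @return numeric matrix, genes x cells, with dimnames
#' @export
readExpression <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "#")
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("expression file contains non-numeric values: ", path)
  if (transpose) M <- t(M)
  M
}

#' Read a pseudo-time table
#'
#' Two-column delimited file: cell label, pseudo-time value.
#'
#' @param path input file
#' @return named numeric vector of pseudo-times
#' @export
readPseudotime <- function(path) {
  if (!file.exists(path)) stop("cannot read pseudotime file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("pseudotime file needs two columns (cell, time)")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a signed edge list
#'
#' Tab-separated columns: regulator, target, then optionally a sign column
#' in `{+1, -1}` and a weight column. Lines starting with `#` are metadata.
#'
#' @param path input file
#' @return data frame with columns `regulator`, `target`, `sign`, `weight`
#'   (`sign` is NA when the file is unsigned)
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs at least regulator and target columns")
  out <- data.frame(regulator = as.character(df[[1]]),
                    target = as.character(df[[2]]),
                    sign = NA_real_, weight = NA_real_,
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 3) out$sign <- as.numeric(df[[3]])
  if (ncol(df) >= 4) out$weight <- as.numeric(df[[4]])
  if (!all(is.na(out$sign)) && !all(out$sign %in% c(-1, 1)))
    stop("sign column must contain only +1/-1")
  out
}

#' Write a signed weighted edge list
#'
#' Serializes the nonzero entries of a weight matrix (or an
#' [InferredNetwork-class]) as TSV `regulator TAB target TAB sign TAB
#' |weight|`, in deterministic target-major order. Metadata lines are
#' prefixed with `#`.
#'
#' @param net an [InferredNetwork-class] or signed weight matrix
#' @param path output file
#' @param metadata optional named list written as `# key: value` header lines
#' @return the edge data frame, invisibly
#' @export
writeEdgeList <- function(net, path, metadata = NULL) {
  W <- if (is(net, "InferredNetwork")) weightMatrix(net) else as.matrix(net)
  genes <- rownames(W)
  if (is.null(genes)) genes <- paste0("x", seq_len(nrow(W)))
  edges <- do.call(rbind, lapply(seq_len(ncol(W)), function(i) {
    k <- which(W[, i] != 0)
    if (!length(k)) return(NULL)
    data.frame(regulator = genes[k], target = genes[i],
               sign = ifelse(W[k, i] > 0, 1L, -1L),
               weight = abs(W[k, i]), stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(regulator = character(0), target = character(0),
                        sign = integer(0), weight = numeric(0))
  con <- file(path, "w"); on.exit(close(con))
  for (key in names(metadata))
    writeLines(sprintf("# %s: %s", key, metadata[[key]]), con)
  utils::write.table(edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(edges)
}

#' Convert an edge list to a signed adjacency matrix
#'
#' Gene identity is matched by name, never by row position. Unsigned edge
#' lists produce `+1` entries.
#'
#' @param edges data frame as returned by [readEdgeList()]
#' @param geneNames gene universe; defaults to the genes present in the list
#' @return N x N matrix in `{-1, 0, +1}`
#' @export
edgesToAdjacency <- function(edges, geneNames = NULL) {
  if (is.null(geneNames))
    geneNames <- sort(unique(c(edges$regulator, edges$target)))
  missing <- setdiff(unique(c(edges$regulator, edges$target)), geneNames)
  if (length(missing))
    stop("genes absent from the gene universe: ", paste(missing, collapse = ", "))
  A <- matrix(0L, length(geneNames), length(geneNames),
              dimnames = list(geneNames, geneNames))
  if (nrow(edges)) {
    s <- ifelse(is.na(edges$sign), 1L, as.integer(edges$sign))
    A[cbind(match(edges$regulator, geneNames),
            match(edges$target, geneNames))] <- s
  }
  A
}

#' Write threshold rules to a text file
#'
#' One line per gene: `gene : [<weighted literal sum> >= <threshold>]`,
#' with inhibition marked by a trailing `~`. Parsed back by [readRules()].
#'
#' @param net a [BooleanThresholdNetwork-class] or [InferredNetwork-class]
#' @param path output file
#' @export
writeRules <- function(net, path) {
  if (is(net, "InferredNetwork")) net <- ruleNetwork(net)
  stopifnot(is(net, "BooleanThresholdNetwork"))
  lines <- vapply(seq_along(net@rules), function(i)
    sprintf("%s : %s", net@geneNames[i],
            ruleToText(net@rules[[i]], net@geneNames)), character(1))
  writeLines(lines, path)
  invisible(lines)
}

#' Read threshold rules from a text file
#'
#' @param path rules file written by [writeRules()]
#' @return a [BooleanThresholdNetwork-class]
#' @export
readRules <- function(path) {
  if (!file.exists(path)) stop("cannot read rules file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed rule line ", bad[1], ": ", lines[bad[1]])
  genes <- trimws(vapply(parts, `[`, character(1), 1))
  ruleList <- lapply(seq_along(parts), function(i) {
    tryCatch(parseRule(parts[[i]][2], genes),
             error = function(e) stop("malformed rule line ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  BooleanThresholdNetwork(ruleList, genes)
}

#' End-to-end inference command
#'
#' Reads an expression matrix (and optional pseudo-time), binarizes,
#' infers the network, and writes the signed edge list, the rules file,
#' per-gene one-step accuracies and a metadata JSON into `outDir`.
#'
#' @param expressionPath delimited expression matrix
#' @param pseudotimePath optional two-column pseudo-time TSV
#' @param outDir output directory (created if needed)
#' @param binarize `"singlecell"`, `"gene_mean"` or `"kmeans2"`
#' @param transpose cells-in-rows input dialect
#' @param ... further arguments passed to [inferNetwork()]
#' @return the [InferredNetwork-class], invisibly
#' @export
cmdInfer <- function(expressionPath, pseudotimePath = NULL, outDir = ".",
                     binarize = c("singlecell", "gene_mean", "kmeans2"),
                     transpose = FALSE, ...) {
  binarize <- match.arg(binarize)
  E <- readExpression(expressionPath, transpose = transpose)
  if (!is.null(pseudotimePath)) {
    pt <- readPseudotime(pseudotimePath)
    if (!all(colnames(E) %in% names(pt)))
      stop("pseudotime file does not cover all cells")
    E <- orderByPseudotime(E, unname(pt[colnames(E)]))
  }
  B <- switch(binarize,
              singlecell = binarizeSingleCell(E),
              gene_mean = binarizeBulk(E, "gene_mean"),
              kmeans2 = binarizeBulk(E, "kmeans2"))
  net <- inferNetwork(B, ...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeEdgeList(net, file.path(outDir, "edges.tsv"),
                metadata = list(seed = net@metadata$seed %||% "NULL",
                                sigma = net@metadata$sigma))
  writeRules(net, file.path(outDir, "rules.txt"))
  pred <- predictStates(net, B)
  dyacc <- rowMeans(pred == B[, -1L, drop = FALSE])
  utils::write.table(
    data.frame(gene = rownames(B), dyacc = dyacc),
    file.path(outDir, "dyacc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(net@metadata, file.path(outDir, "metadata.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(net)
}

#' Evaluate a predicted edge list against a gold standard
#'
#' @param predPath predicted signed edge list TSV
#' @param goldPath gold-standard edge list TSV
#' @param signMode `"SIGN0"` or `"SIGN1"` (the latter requires signs in the
#'   gold file)
#' @param outPath optional path for a metrics JSON
#' @return an [EvaluationReport-class]
#' @export
cmdEvaluate <- function(predPath, goldPath, signMode = c("SIGN0", "SIGN1"),
                        outPath = NULL) {
  signMode <- match.arg(signMode)
  pred <- readEdgeList(predPath)
  gold <- readEdgeList(goldPath)
  if (signMode == "SIGN1" && all(is.na(gold$sign)))
    stop("SIGN1 evaluation requires a sign column in the gold standard")
  genes <- sort(unique(c(pred$regulator, pred$target,
                         gold$regulator, gold$target)))
  W <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (nrow(pred))
    W[cbind(match(pred$regulator, genes), match(pred$target, genes))] <-
      ifelse(is.na(pred$sign), 1, pred$sign) *
      ifelse(is.na(pred$weight), 1, pred$weight)
  G <- edgesToAdjacency(gold, genes)
  rep_ <- evaluateNetwork(W, G, signMode)
  if (!is.null(outPath))
    jsonlite::write_json(as.list(reportMetrics(rep_)),
                         outPath, auto_unbox = TRUE, digits = NA)
  rep_
}

#' Simulate a rules file
#'
#' @param rulesPath rules text file (see [writeRules()])
#' @param init initial state: a 0/1 vector, or `"zeros"`/`"ones"`
#' @param steps number of synchronous steps (0 echoes the initial state)
#' @param outPath optional TSV output (genes x steps+1)
#' @return the trajectory matrix
#' @export
cmdSimulate <- function(rulesPath, init = "zeros", steps = 10,
                        outPath = NULL) {
  net <- readRules(rulesPath)
  if (is.character(init))
    init <- switch(match.arg(init, c("zeros", "ones")),
                   zeros = rep(0L, length(net)), ones = rep(1L, length(net)))
  traj <- if (steps == 0) {
    matrix(as.integer(init), ncol = 1, dimnames = list(net@geneNames, NULL))
  } else {
    simulateTrajectory(net, init, steps)
  }
  if (!is.null(outPath))
    utils::write.table(traj, outPath, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = FALSE)
  traj
}

#' Write the synthetic benchmark to disk
#'
#' @param outDir output directory
#' @param delta flip-noise probability
#' @param seed integer seed
#' @return paths of the written files, invisibly
#' @export
cmdSynth <- function(outDir = ".", delta = 0, seed = NULL) {
  bench <- generateBenchmark(delta = delta, seed = seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outDir, c("states.tsv", "successors.tsv",
                               "gold_edges.tsv", "synth_metadata.json"))
  utils::write.table(bench$X, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bench$Y, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeEdgeList(bench$gold, paths[3])
  jsonlite::write_json(list(seed = seed, delta = delta,
                            observations = nrow(bench$X),
                            genes = ncol(bench$X)),
                       paths[4], auto_unbox = TRUE, null = "null", digits = NA)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
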
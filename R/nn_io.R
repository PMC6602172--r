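#' Save a fitted neural network as a flat text archive
#'
#' Writes a plain-text, inspectable archive: key-value header lines
#' (architecture, activation, best epoch, feature names) followed by each
#' layer's weight matrix and bias vector as tab-separated blocks. Numbers are
#' written at full double precision so [read_nnreg()] round-trips exactly.
#'
#' @param object an [nnreg()] fit.
#' @param path output file path.
#' @export
write_nnreg <- function(object, path) {
  stopifnot(inherits(object, "nnreg"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  writeLines("# ecodriver nnreg archive v1", con)
  writeLines(paste("architecture:",
                   paste(object$architecture, collapse = " ")), con)
  writeLines(paste("activation:", object$activation), con)
  writeLines(paste("best_epoch:", object$best_epoch), con)
  writeLines(paste("feature_names:",
                   paste(object$feature_names, collapse = "\t")), con)
  for (l in seq_along(object$weights)) {
    W <- object$weights[[l]]
    writeLines(sprintf("W%d %d %d", l, nrow(W), ncol(W)), con)
    writeLines(apply(W, 1, function(r) paste(num(r), collapse = "\t")), con)
    b <- object$biases[[l]]
    writeLines(sprintf("b%d %d", l, length(b)), con)
    writeLines(paste(num(b), collapse = "\t"), con)
  }
  invisible(path)
}

#' Load a neural network from a flat text archive
#' @param path path written by [write_nnreg()].
#' @return an object usable with [predict.nnreg()], [nn_sensitivity()] etc.
#'   (training history is not stored in the archive).
#' @export
read_nnreg <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# ecodriver nnreg archive"))
    stop("not an nnreg archive: ", path)
  kv <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)[1]
    sub(paste0("^", key, ":\\s*"), "", ln)
  }
  arch <- as.integer(strsplit(kv("architecture"), " ")[[1]])
  feats <- strsplit(kv("feature_names"), "\t")[[1]]
  L <- length(arch) - 1
  weights <- biases <- vector("list", L)
  i <- 1
  for (l in seq_len(L)) {
    i <- grep(sprintf("^W%d ", l), lines)[1]
    dims <- as.integer(strsplit(lines[i], " ")[[1]][2:3])
    block <- lines[(i + 1):(i + dims[1])]
    weights[[l]] <- matrix(as.numeric(unlist(strsplit(block, "\t"))),
                           dims[1], dims[2], byrow = TRUE)
    j <- grep(sprintf("^b%d ", l), lines)[1]
    biases[[l]] <- as.numeric(strsplit(lines[j + 1], "\t")[[1]])
  }
  structure(list(weights = weights, biases = biases, architecture = arch,
                 activation = kv("activation"),
                 best_epoch = as.integer(kv("best_epoch")),
                 feature_names = feats,
                 config = list(), trace = NULL),
            class = "nnreg")
}
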
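`%||%` <- function(a, b) if (is.null(a)) b else a

# product of `terms` grouped by integer index `idx` over 1..n, empty group -> 1
prodByGroup <- function(terms, idx, n) {
  out <- rep(1, n)
  if (length(terms)) {
    # exp(rowsum(log(.))) is exact for terms in [0,1]; log(0) = -Inf -> 0
    s <- rowsum(log(terms), group = idx)
    out[as.integer(rownames(s))] <- exp(s[, 1L])
  }
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

readTsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character", ...)
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

stripChr <- function(x) sub("^chr", "", x, ignore.case = TRUE)
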
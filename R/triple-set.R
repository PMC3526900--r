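#' Sets of rooted triples
#'
#' A rooted triple \code{((x,y),z)} is a binary tree on three leaves with
#' cherry \code{\{x,y\}} and outgroup \code{z}. A triple set has set
#' semantics: the cherry is unordered (\code{((x,y),z) == ((y,x),z)}) and
#' duplicates are collapsed. Internally stored as a data frame with character
#' columns \code{x}, \code{y}, \code{z}, canonicalized so that \code{x <= y}.
#'
#' @param x,y,z character vectors of equal length; row i encodes
#'   \code{((x[i],y[i]),z[i])}.
#' @return an object of class \code{c("triple_set","data.frame")}.
#' @examples
#' triple_set(c("a","b"), c("b","a"), c("c","c"))  # one triple, two spellings
#' @export
triple_set <- function(x = character(0), y = character(0), z = character(0)) {
  x <- as.character(x); y <- as.character(y); z <- as.character(z)
  stopifnot(length(x) == length(y), length(y) == length(z))
  bad <- x == y | x == z | y == z
  if (any(bad))
    stop("triples must have three pairwise distinct labels (row ",
         which(bad)[1L], ")")
  swap <- x > y
  tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
  df <- unique(data.frame(x = x, y = y, z = z, stringsAsFactors = FALSE))
  df <- df[order(df$x, df$y, df$z), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("triple_set", "data.frame")
  df
}

#' @export
print.triple_set <- function(x, ...) {
  cat("Set of", nrow(x), "rooted triples")
  if (nrow(x)) {
    cat(":\n")
    cat(paste0("  ((", x$x, ",", x$y, "),", x$z, ")"), sep = "\n")
  } else cat(" (empty)\n")
  invisible(x)
}

#' @rdname triple_set
#' @param df a data frame with columns \code{x}, \code{y}, \code{z}.
#' @export
as_triple_set <- function(df) {
  triple_set(df$x, df$y, df$z)
}

#' Union of triple sets
#' @param ... \code{triple_set} objects.
#' @return a \code{triple_set}.
#' @export
triples_union <- function(...) {
  parts <- list(...)
  as_triple_set(do.call(rbind, lapply(parts, as.data.frame)))
}

#' Set equality of two triple sets
#' @param a,b \code{triple_set} objects.
#' @return logical.
#' @export
triples_equal <- function(a, b) {
  nrow(a) == nrow(b) && all(triple_key(a) == triple_key(b))
}

triple_key <- function(ts) paste(ts$x, ts$y, ts$z, sep = "\r")

#' Labels occurring in a triple set
#' @param ts a \code{triple_set}.
#' @return sorted character vector of distinct labels.
#' @export
triple_labels <- function(ts) {
  sort(unique(c(ts$x, ts$y, ts$z)))
}

#' Read / write triple sets as TSV
#'
#' Three tab-separated columns \code{x y z} meaning \code{((x,y),z)}; lines
#' starting with \code{#} are comments.
#'
#' @param file path.
#' @return \code{read_triples}: a \code{triple_set}.
#' @export
read_triples <- function(file) {
  ln <- readLines(file)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!length(ln)) return(triple_set())
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed triple TSV: expected 3 tab-separated columns")
  m <- do.call(rbind, parts)
  triple_set(m[, 1L], m[, 2L], m[, 3L])
}

#' @rdname read_triples
#' @param ts a \code{triple_set} to write.
#' @export
write_triples <- function(ts, file) {
  writeLines(c("# x\ty\tz  meaning ((x,y),z)",
               paste(ts$x, ts$y, ts$z, sep = "\t")), file)
  invisible(file)
}
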
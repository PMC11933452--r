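#' Deterministic stub embedding backend
#'
#' Maps each word token to a pseudo-random unit vector seeded by a stable
#' hash of the token, so equal tokens always map to equal vectors across
#' sessions and platforms. Intended for tests and for exercising the
#' semantic-diversity machinery without bundling an external sentence-
#' embedding model; it carries no real semantics. A real multilingual
#' sentence-embedding backend plugs in through the same provider contract
#' (see [file_embedding()]).
#'
#' @param dim embedding dimensionality (default 16).
#' @return An `embedding_provider` with `backend_id = "stub"`.
#' @export
stub_embedding <- function(dim = 16L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L)
  lookup <- function(token) {
    with_seed(hash_string(token) %% 2147483646L + 1L, {
      v <- rnorm(dim)
      v / sqrt(sum(v^2))
    })
  }
  new_embedding_provider("stub", lookup)
}

#' File-backed embedding backend
#'
#' Reads a TSV of precomputed word vectors (first column the token, the
#' remaining columns the vector components). This is the adapter seam for
#' external embedding models: export vectors once, then score offline.
#'
#' @param path TSV file, no header.
#' @return An `embedding_provider` with `backend_id = "file:<path>"`.
#' @export
file_embedding <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 3L)
  vecs <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vecs) <- as.character(tab[[1]])
  lookup <- function(token) {
    if (!token %in% rownames(vecs)) return(NULL)
    as.numeric(vecs[token, ])
  }
  new_embedding_provider(paste0("file:", path), lookup)
}

new_embedding_provider <- function(backend_id, lookup) {
  structure(list(backend_id = backend_id, lookup = lookup),
            class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat("<embedding_provider> backend:", x$backend_id, "\n")
  invisible(x)
}

#' Mean pairwise semantic distance of a stimulus
#'
#' Embeds every unique word type of the stimulus and returns the mean of
#' 1 - cosine similarity over all unordered pairs of types. Depends only on
#' the set of unique types, not on token order or repetition; a single-type
#' text has diversity 0 by definition.
#'
#' @inheritParams prefix_entropy
#' @param provider an embedding provider ([stub_embedding()] or
#'   [file_embedding()]).
#' @return Scalar in [0, 2].
#' @export
semantic_diversity <- function(stimulus, provider = stub_embedding()) {
  tokens <- as_tokens(stimulus)
  types <- unique(tokens)
  if (length(types) == 1L) return(0)
  vecs <- lapply(types, provider$lookup)
  missing <- types[vapply(vecs, is.null, logical(1))]
  if (length(missing) > 0L) {
    stop("embedding backend '", provider$backend_id,
         "' cannot resolve token(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, vecs)
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) stop("zero-norm embedding vector", call. = FALSE)
  cosine <- tcrossprod(m / norms)
  d <- 1 - cosine[upper.tri(cosine)]
  mean(d)
}
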
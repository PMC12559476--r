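## Per-residue featurizers ("embedders"). The toolkit ships a
## deterministic physicochemical/one-hot fallback that needs no model
## download; transformer protein language models (e.g. ProtTrans-X5) plug
## in through the same registry with externally computed matrices.

.embedderRegistry <- new.env(parent = emptyenv())

## fallback per-residue feature table: one-hot(20) + four z-scaled
## physicochemical scales (Kyte-Doolittle hydrophobicity, residue volume,
## Grantham polarity, net charge at pH 7)
.aaPropertyTable <- function() {
  aa <- .STANDARD_AA
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  vol <- c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1,
           H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
           P = 112.7, Q = 143.8, R = 173.4, S = 89.0, T = 116.1, V = 140.0,
           W = 227.8, Y = 193.6)
  pol <- c(A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0, H = 10.4,
           I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6, P = 8.0, Q = 10.5,
           R = 10.5, S = 9.2, T = 8.6, V = 5.9, W = 5.4, Y = 6.2)
  chg <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1, I = 0, K = 1,
           L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
           W = 0, Y = 0)
  onehot <- diag(1, length(aa))
  dimnames(onehot) <- list(aa, paste0("is_", aa))
  scales <- cbind(hydropathy = as.numeric(scale(kd[aa])),
                  volume = as.numeric(scale(vol[aa])),
                  polarity = as.numeric(scale(pol[aa])),
                  charge = as.numeric(scale(chg[aa])))
  rownames(scales) <- aa
  tab <- cbind(onehot, scales)
  ## X (unknown) contributes the column means of zero (one-hot) and zero
  ## (centred scales): an uninformative residue
  tab <- rbind(tab, X = 0)
  rownames(tab)[nrow(tab)] <- "X"
  tab
}

#' Register a per-residue embedder
#'
#' An embedder is a function `f(residues)` taking a plain character
#' string and returning an `L x d` numeric matrix (one row per residue)
#' with a fixed column count `d` regardless of sequence length.
#'
#' @param tag short unique name, e.g. `"fallback-physchem"` or
#'   `"prottrans-x5"`.
#' @param fun the per-residue featurizer function.
#' @param dim declared output dimension `d`.
#' @param alphabet characters the embedder accepts (default the 20
#'   standard residues plus `X`).
#' @return invisibly, `tag`.
#' @seealso [listEmbedders()], [embedEnzyme()]
#' @export
registerEmbedder <- function(tag, fun, dim,
                             alphabet = c(.STANDARD_AA, "X")) {
  stopifnot(is.character(tag), length(tag) == 1L, is.function(fun),
            dim >= 1L)
  assign(tag, list(fun = fun, dim = as.integer(dim), alphabet = alphabet),
         envir = .embedderRegistry)
  invisible(tag)
}

#' @rdname registerEmbedder
#' @export
listEmbedders <- function() sort(ls(.embedderRegistry))

.getEmbedder <- function(tag) {
  if (!exists(tag, envir = .embedderRegistry, inherits = FALSE))
    stop("unknown embedder '", tag, "'; registered embedders: ",
         paste(listEmbedders(), collapse = ", "))
  get(tag, envir = .embedderRegistry, inherits = FALSE)
}

.registerBuiltinEmbedders <- function() {
  tab <- .aaPropertyTable()
  registerEmbedder("fallback-physchem",
                   function(residues) {
                     letters <- strsplit(residues, "")[[1]]
                     tab[letters, , drop = FALSE]
                   },
                   dim = ncol(tab))
}

#' The fallback per-residue feature table
#'
#' The deterministic per-residue feature table behind the
#' `"fallback-physchem"` embedder: one-hot encoding of the 20 standard
#' residues plus z-scaled hydropathy (Kyte-Doolittle), volume, polarity
#' (Grantham) and net charge at pH 7; the unknown residue `X` maps to the
#' zero row.
#'
#' @return a 21 x 24 numeric matrix (rows residues, columns features).
#' @export
fallbackFeatureTable <- function() .aaPropertyTable()

#' Embed an enzyme by mean-pooled per-residue features
#'
#' Computes the embedder's `L x d` per-residue matrix and mean-pools over
#' residues into a single length-`d` vector, the standard fixed-length
#' protein representation for downstream classifiers.
#'
#' @param seq a single sequence (character, [Biostrings::AAString] or
#'   length-1 [Biostrings::AAStringSet]).
#' @param embedder registered embedder tag (default
#'   `"fallback-physchem"`).
#' @return a numeric vector of length `d` with attributes `embedder_tag`
#'   and `dim`.
#' @examples
#' v <- embedEnzyme("ACD")
#' length(v)  # 24
#' @export
embedEnzyme <- function(seq, embedder = "fallback-physchem") {
  e <- .getEmbedder(embedder)
  residues <- as.character(.asAAString(seq))
  if (!nzchar(residues)) stop("embedEnzyme: empty sequence")
  letters <- unique(strsplit(residues, "")[[1]])
  bad <- setdiff(letters, e$alphabet)
  if (length(bad))
    stop("residue(s) outside embedder alphabet: ",
         paste(bad, collapse = ", "))
  m <- e$fun(residues)
  if (ncol(m) != e$dim)
    stop("embedder '", embedder, "' returned dimension ", ncol(m),
         ", declared ", e$dim)
  v <- colMeans(m)
  attr(v, "embedder_tag") <- embedder
  attr(v, "dim") <- e$dim
  v
}

#' Embed a collection of enzymes
#'
#' @param seqs an [Biostrings::AAStringSet] with unique names.
#' @param embedder registered embedder tag.
#' @return a numeric matrix, one row per sequence (rownames the ids),
#'   with attribute `embedder_tag`.
#' @export
featurizeEnzymes <- function(seqs, embedder = "fallback-physchem") {
  stopifnot(is(seqs, "AAStringSet"))
  e <- .getEmbedder(embedder)
  m <- t(vapply(seq_along(seqs),
                function(i) as.numeric(embedEnzyme(seqs[[i]], embedder)),
                numeric(e$dim)))
  rownames(m) <- names(seqs)
  attr(m, "embedder_tag") <- embedder
  m
}
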
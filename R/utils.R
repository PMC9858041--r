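# Internal numerical helpers shared across modules.

#' Row-wise log-sum-exp
#'
#' @param m numeric matrix.
#' @return numeric vector, `log(rowSums(exp(m)))` computed stably.
#' @keywords internal
#' @noRd
logsumexp_rows <- function(m) {
  mx <- do.call(pmax, c(lapply(seq_len(ncol(m)), function(j) m[, j]), list(na.rm = FALSE)))
  mx + log(rowSums(exp(m - mx)))
}

#' Softmax of a logit vector with an implicit reference zero appended
#' @noRd
softmax_ref <- function(theta) {
  z <- c(theta, 0)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Stable 31-bit string hash (FNV-1a variant), for per-subject RNG streams
#' @noRd
stable_id_hash <- function(id) {
  bytes <- utf8ToInt(as.character(id))
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(h, b)
    # multiply by the FNV prime modulo 2^31 - 1 without overflow
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

#' All permutations of 1..k (k! rows); used for optimal class matching
#' @noRd
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k)
  for (pos in seq_len(k)) {
    block <- matrix(0L, nrow(sub), k)
    block[, pos] <- k
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

#' Stop with a consistent error class
#' @noRd
ht_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "hba1ctraj_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
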
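# Synthetic binary profile matrices with planted correlated components.
# Each planted component is a block: a subset of substructure columns and a
# subset of side-effect columns that light up together on a random carrier
# subset of drugs. Planted bits are corrupted by symmetric bit flips; all
# other cells are independent Bernoulli background noise, emulating the
# sparse, noisy co-occurrence structure of fingerprint/side-effect data.

#' Describe one planted latent component
#'
#' @param sub_support integer indices of the substructure (X) columns the
#'   component occupies.
#' @param se_support integer indices of the side-effect (Y) columns.
#' @param drug_frac fraction of drugs carrying the component (0 < f < 1).
#' @param flip_noise probability that any planted bit is flipped
#'   (0 <= noise < 0.5).
#' @return object of class `planted_component`.
#' @export
planted_component <- function(sub_support, se_support, drug_frac,
                              flip_noise = 0) {
  sub_support <- as.integer(sub_support)
  se_support <- as.integer(se_support)
  if (length(sub_support) == 0L || length(se_support) == 0L)
    stop("component supports must be non-empty", call. = FALSE)
  if (anyDuplicated(sub_support) || anyDuplicated(se_support))
    stop("support indices must be unique", call. = FALSE)
  if (drug_frac <= 0 || drug_frac >= 1)
    stop("drug_frac must be in (0, 1)", call. = FALSE)
  if (flip_noise < 0 || flip_noise >= 0.5)
    stop("flip_noise must be in [0, 0.5)", call. = FALSE)
  structure(list(sub_support = sub_support, se_support = se_support,
                 drug_frac = drug_frac, flip_noise = flip_noise),
            class = "planted_component")
}

check_supports <- function(components, p, q) {
  subs <- unlist(lapply(components, `[[`, "sub_support"))
  ses <- unlist(lapply(components, `[[`, "se_support"))
  if (length(subs) && (min(subs) < 1L || max(subs) > p))
    stop("sub_support indices outside 1..p", call. = FALSE)
  if (length(ses) && (min(ses) < 1L || max(ses) > q))
    stop("se_support indices outside 1..q", call. = FALSE)
  if (anyDuplicated(subs))
    stop("components have overlapping substructure supports", call. = FALSE)
  if (anyDuplicated(ses))
    stop("components have overlapping side-effect supports", call. = FALSE)
}

drug_ids <- function(n) sprintf("drug%04d", seq_len(n))

#' Generate binary X/Y matrices with planted correlated components
#'
#' Every cell starts as independent Bernoulli(`background_rate`) noise. For
#' each component, a carrier subset of `round(drug_frac * n)` drugs is drawn
#' without replacement; their cells on the component's support columns are
#' set to 1 and then flipped with probability `flip_noise`. Components may
#' share carrier drugs but never support columns.
#'
#' @param n,p,q numbers of drugs, substructure bits and side-effect terms.
#' @param components list of [planted_component()] objects.
#' @param background_rate Bernoulli rate for unplanted cells (0 <= r < 0.5).
#' @param seed integer RNG seed; the output is a pure function of the
#'   arguments.
#' @return list with binary matrices `X` (n x p), `Y` (n x q) and `truth`,
#'   a `planted_ground_truth` holding the components and their carrier row
#'   indices.
#' @export
generate_planted_dataset <- function(n, p, q, components = list(),
                                     background_rate = 0.05, seed = 1) {
  stopifnot(n >= 1, p >= 1, q >= 1)
  if (background_rate < 0 || background_rate >= 0.5)
    stop("background_rate must be in [0, 0.5)", call. = FALSE)
  check_supports(components, p, q)
  set.seed(seed)
  X <- matrix(stats::rbinom(n * p, 1L, background_rate), n, p)
  Y <- matrix(stats::rbinom(n * q, 1L, background_rate), n, q)
  members <- vector("list", length(components))
  for (ci in seq_along(components)) {
    comp <- components[[ci]]
    m <- sort(sample.int(n, round(comp$drug_frac * n)))
    members[[ci]] <- m
    keep <- 1 - comp$flip_noise  # planted bit survives the flip
    X[m, comp$sub_support] <-
      stats::rbinom(length(m) * length(comp$sub_support), 1L, keep)
    Y[m, comp$se_support] <-
      stats::rbinom(length(m) * length(comp$se_support), 1L, keep)
  }
  dimnames(X) <- list(drug_ids(n), sprintf("fp%03d", seq_len(p)))
  dimnames(Y) <- list(drug_ids(n), sprintf("se%03d", seq_len(q)))
  truth <- structure(list(components = components, member_drugs = members),
                     class = "planted_ground_truth")
  list(X = X, Y = Y, truth = truth)
}

#' Generate independent Bernoulli X/Y matrices (no signal)
#'
#' Null model for calibration: every cell of X and Y is i.i.d.
#' Bernoulli(`rate`) and the two matrices are independent.
#'
#' @param n,p,q matrix dimensions.
#' @param rate Bernoulli rate in [0, 1).
#' @param seed integer RNG seed.
#' @return list with matrices `X` and `Y`.
#' @export
generate_null_dataset <- function(n, p, q, rate = 0.1, seed = 1) {
  stopifnot(n >= 1, p >= 1, q >= 1)
  if (rate < 0 || rate >= 1)
    stop("rate must be in [0, 1)", call. = FALSE)
  set.seed(seed)
  X <- matrix(stats::rbinom(n * p, 1L, rate), n, p,
              dimnames = list(drug_ids(n), sprintf("fp%03d", seq_len(p))))
  Y <- matrix(stats::rbinom(n * q, 1L, rate), n, q,
              dimnames = list(drug_ids(n), sprintf("se%03d", seq_len(q))))
  list(X = X, Y = Y)
}
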
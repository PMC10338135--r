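#' Stationary Markov-chain sequence model
#'
#' An order-d chain over {A, C, G, T}: a `4^d x 4` transition matrix giving
#' the distribution of the next base for each length-d context, plus an
#' initial distribution over the `4^d` contexts. Rows must sum to 1.
#'
#' @param transition Numeric matrix, `4^d` rows (contexts in code order)
#'   and 4 columns (next base A, C, G, T).
#' @param initial Optional initial distribution over contexts; defaults to
#'   uniform.
#' @return An object of class `"transition_model"` with elements `order`,
#'   `transition`, `initial`.
#' @examples
#' # deterministic cycle A -> C -> G -> T -> A
#' P <- matrix(0, 4, 4); P[cbind(1:4, c(2, 3, 4, 1))] <- 1
#' m <- transition_model(P, initial = c(1, 0, 0, 0))
#' simulate_sequence(m, 8, seed = 1)  # "ACGTACGT"
#' @export
transition_model <- function(transition, initial = NULL) {
  stopifnot(is.matrix(transition), ncol(transition) == 4L)
  nr <- nrow(transition)
  order <- as.integer(round(log(nr, base = 4)))
  if (order < 1L || 4^order != nr) {
    stop("transition matrix must have 4^d rows for some order d >= 1",
         call. = FALSE)
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition rows must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(initial)) initial <- rep(1 / nr, nr)
  stopifnot(length(initial) == nr)
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-8) {
    stop("initial distribution must be non-negative and sum to 1", call. = FALSE)
  }
  rownames(transition) <- all_mers(order)
  colnames(transition) <- DNA_BASES
  structure(list(order = order, transition = transition,
                 initial = as.numeric(initial)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("order-%d stationary Markov chain (%d contexts)\n",
              x$order, nrow(x$transition)))
  if (nrow(x$transition) <= 16L) print(round(x$transition, 3))
  invisible(x)
}

#' Random transition model with Dirichlet rows
#'
#' Draws each transition row (and the initial distribution) independently
#' from a symmetric Dirichlet; the concentration controls how far rows sit
#' from uniform (1 = flat Dirichlet).
#'
#' @param order Chain order d >= 1.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration parameter, > 0.
#' @return A [transition_model()].
#' @export
random_transition_model <- function(order, seed, concentration = 1) {
  stopifnot(order >= 1, concentration > 0)
  nr <- as.integer(4^order)
  set.seed(as.integer(seed))
  g <- matrix(stats::rgamma(nr * 4L, shape = concentration), nrow = nr)
  init <- stats::rgamma(nr, shape = concentration)
  transition_model(g / rowSums(g), initial = init / sum(init))
}

#' Simulate a nucleotide sequence from a Markov chain
#'
#' The first d bases are the initial context drawn from the model's initial
#' distribution; every following base is drawn from the transition row of
#' the current length-d context. Fully reproducible per seed.
#'
#' @param model A [transition_model()].
#' @param length Sequence length in bp, >= the model order.
#' @param seed Integer seed.
#' @return A nucleotide string of the requested length.
#' @export
simulate_sequence <- function(model, length, seed) {
  stopifnot(inherits(model, "transition_model"))
  d <- model$order
  if (length < d) stop("length must be at least the model order", call. = FALSE)
  set.seed(as.integer(seed))
  ctx <- sample.int(nrow(model$transition), 1L, prob = model$initial) - 1L
  digits <- integer(length)
  digits[seq_len(d)] <- as.integer(mer_to_digit_vector(decode_mer(ctx, d)))
  if (length > d) {
    cum <- t(apply(model$transition, 1L, cumsum))
    cum3 <- cum[, 1:3, drop = FALSE]  # last column is always 1
    base_mod <- as.integer(4^(d - 1L))
    u <- stats::runif(length - d)
    for (i in (d + 1L):length) {
      b <- findInterval(u[i - d], cum3[ctx + 1L, ])
      digits[i] <- b
      ctx <- (ctx %% base_mod) * 4L + b
    }
  }
  paste(DNA_BASES[digits + 1L], collapse = "")
}

#' Perturb a transition model toward a random one
#'
#' Mixes each transition row with an independent seeded random stochastic
#' row: `(1 - epsilon) * row + epsilon * random_row`. `epsilon = 0` leaves
#' the model unchanged; `epsilon = 1` replaces every row. Used to
#' manufacture a second class at a controlled separation from the first.
#'
#' @param model A [transition_model()].
#' @param epsilon Mixing weight in `[0, 1]` (the class-separation knob).
#' @param seed Integer seed for the random rows.
#' @return A new [transition_model()] with the same order and initial
#'   distribution.
#' @export
perturb_model <- function(model, epsilon, seed) {
  stopifnot(inherits(model, "transition_model"),
            epsilon >= 0, epsilon <= 1)
  set.seed(as.integer(seed))
  nr <- nrow(model$transition)
  g <- matrix(stats::rgamma(nr * 4L, shape = 1), nrow = nr)
  rnd <- g / rowSums(g)
  transition_model((1 - epsilon) * model$transition + epsilon * rnd,
                   initial = model$initial)
}

# Deterministic per-item sub-seed fan-out from one master seed.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483629) + 1L
}

#' Simulate a labeled two-class sequence dataset
#'
#' Draws `n_per_class` independent sequences from each of two chain models.
#' Each sequence gets its own sub-seed derived from the master seed by a
#' counter, so the dataset is reproducible and order-independent. With
#' `model_b = model_a` the dataset carries no class signal (the null
#' benchmark).
#'
#' @param model_a,model_b [transition_model()]s for the two classes.
#' @param n_per_class Sequences per class, >= 1.
#' @param length Sequence length in bp.
#' @param seed Master integer seed.
#' @param class_names Length-2 character vector of class labels.
#' @return A records data frame with columns `id`, `description`,
#'   `sequence`, `class`.
#' @export
make_two_class_dataset <- function(model_a, model_b, n_per_class, length,
                                   seed, class_names = c("A", "B")) {
  stopifnot(n_per_class >= 1, length(class_names) == 2L)
  models <- list(model_a, model_b)
  parts <- lapply(1:2, function(cl) {
    seqs <- vapply(seq_len(n_per_class), function(i) {
      simulate_sequence(models[[cl]], length,
                        seed = derive_seed(seed, (cl - 1L) * n_per_class + i))
    }, character(1L))
    data.frame(
      id = sprintf("%s_%04d", class_names[cl], seq_len(n_per_class)),
      description = "",
      sequence = seqs,
      class = class_names[cl],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, parts)
}

#' Write the label file accompanying a simulated dataset
#'
#' Two tab-separated columns (id, class), no header.
#'
#' @param records A records data frame with a `class` column.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_labels <- function(records, path) {
  stopifnot("class" %in% names(records))
  utils::write.table(records[, c("id", "class")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
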
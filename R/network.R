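# ---------------------------------------------------------------------------
# Excitatory-inhibitory continuous-time RNN with actor and critic readouts
#
# Rate dynamics (Euler, alpha = dt/tau):
#   r <- relu( (1-alpha) r + alpha (W_rec r + W_in u + b + noise) )
# Dale's law is enforced by a magnitude reparametrization: free parameters
# are unconstrained; the effective recurrent weight is |w| times the sign
# of the presynaptic cell type, and all long-range (input/output) weights
# are |w| (non-negative).
# ---------------------------------------------------------------------------

#' Network configuration
#'
#' @param n Number of recurrent neurons.
#' @param frac_exc Fraction of excitatory neurons (the rest inhibitory).
#' @param tau_ms Single-unit time constant (ms).
#' @param dt_ms Simulation step (ms).
#' @param sigma_rec Recurrent noise amplitude.
#' @param sigma_in Input noise amplitude.
#' @param n_in Number of input channels.
#' @param n_actions Number of policy outputs (hold + 3 choice slots).
#' @return List of class \code{network_config}.
#' @export
network_config <- function(n = 256, frac_exc = 0.8, tau_ms = 100,
                           dt_ms = 20, sigma_rec = 0.15, sigma_in = 0.01,
                           n_in = 16, n_actions = 4) {
  stopifnot(dt_ms > 0, dt_ms <= tau_ms, frac_exc > 0, frac_exc < 1)
  structure(list(n = as.integer(n), frac_exc = frac_exc,
                 n_exc = as.integer(round(frac_exc * n)),
                 tau_ms = tau_ms, dt_ms = dt_ms, alpha = dt_ms / tau_ms,
                 sigma_rec = sigma_rec, sigma_in = sigma_in,
                 n_in = as.integer(n_in), n_actions = as.integer(n_actions)),
            class = "network_config")
}

#' Spectral radius of a matrix
#' @param M Square matrix.
#' @return Largest eigenvalue magnitude.
#' @export
spectral_radius <- function(M) {
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Initialize network parameters
#'
#' Recurrent weights are sampled from a Gamma distribution (shape 4, scale
#' 4), rescaled so the spectral radius of the (pre-mask) matrix is 1.5,
#' and then signed by the Dale mask (excitatory columns positive,
#' inhibitory negative). Input weights are uniform on \code{[0, 1/n_in]};
#' actor and critic output weights uniform on \code{[0, 0.4/n]}; all
#' biases zero.
#'
#' @param cfg A \code{network_config}.
#' @return Object of class \code{ei_network} holding free parameters
#'   (magnitudes), the Dale sign vector and the configuration.
#' @export
init_network <- function(cfg = network_config()) {
  n <- cfg$n
  dale_sign <- c(rep(1, cfg$n_exc), rep(-1, n - cfg$n_exc))
  W <- matrix(stats::rgamma(n * n, shape = 4, scale = 4), n, n)
  W <- W * (1.5 / spectral_radius(W))
  net <- structure(list(
    cfg = cfg,
    dale_sign = dale_sign,
    # free parameters: magnitudes (signs supplied by masks)
    W_rec = W,
    W_in = matrix(stats::runif(n * cfg$n_in, 0, 1 / cfg$n_in), n, cfg$n_in),
    W_a = matrix(stats::runif(cfg$n_actions * n, 0, 0.4 / n),
                 cfg$n_actions, n),
    W_c = matrix(stats::runif(n, 0, 0.4 / n), 1, n),
    b = numeric(n), b_a = numeric(cfg$n_actions), b_c = 0,
    lesion = NULL
  ), class = "ei_network")
  net
}

#' Effective (constraint-obeying) weights
#'
#' Applies the magnitude reparametrization: recurrent columns carry the
#' presynaptic neuron's sign, long-range matrices are non-negative. Any
#' active lesion (recurrent removal) is applied here.
#'
#' @param net An \code{ei_network}.
#' @return List with \code{W_rec}, \code{W_in}, \code{W_a}, \code{W_c}.
#' @export
effective_weights <- function(net) {
  W_rec <- sweep(abs(net$W_rec), 2, net$dale_sign, `*`)
  if (!is.null(net$lesion) && net$lesion$type == "recurrent_removal")
    W_rec[] <- 0
  list(W_rec = W_rec, W_in = abs(net$W_in),
       W_a = abs(net$W_a), W_c = abs(net$W_c))
}

#' Re-impose the sign constraints on a network
#'
#' With the default magnitude parametrization the constraints hold by
#' construction for any free-parameter values, so this is the identity on
#' effective weights and idempotent. The \code{"clip"} variant instead
#' zeroes sign-violating entries of the free parameters.
#'
#' @param net An \code{ei_network}.
#' @param variant \code{"magnitude"} (default) or \code{"clip"}.
#' @return Network with valid constraints.
#' @export
enforce_dale <- function(net, variant = c("magnitude", "clip")) {
  variant <- match.arg(variant)
  if (variant == "clip") {
    net$W_rec[net$W_rec < 0] <- 0
    net$W_in[net$W_in < 0] <- 0
    net$W_a[net$W_a < 0] <- 0
    net$W_c[net$W_c < 0] <- 0
  }
  net
}

#' One Euler step of the rate dynamics
#'
#' @param net An \code{ei_network}.
#' @param r Rate matrix (n x batch) or vector.
#' @param u Input matrix (n_in x batch) or vector (noise, if any, already
#'   included in \code{u}).
#' @param xi Optional pre-drawn standard-normal recurrent noise (n x
#'   batch); \code{NULL} for noiseless dynamics.
#' @param weights Optional precomputed \code{effective_weights(net)}.
#' @return Updated non-negative rate matrix.
#' @export
step_rates <- function(net, r, u, xi = NULL, weights = NULL) {
  cfg <- net$cfg
  w <- if (is.null(weights)) effective_weights(net) else weights
  r <- as.matrix(r); u <- as.matrix(u)
  drive <- w$W_rec %*% r + w$W_in %*% u + net$b
  if (!is.null(xi))
    drive <- drive + cfg$sigma_rec * sqrt(2 / cfg$alpha) * xi
  z <- (1 - cfg$alpha) * r + cfg$alpha * drive
  if (!all(is.finite(z))) stop("non-finite rates: dynamics diverged")
  r_new <- pmax(z, 0)
  if (!is.null(net$lesion) && net$lesion$type == "clamp")
    r_new[net$lesion$neurons, ] <- 0
  r_new
}

#' Actor and critic readouts
#'
#' @param net An \code{ei_network}.
#' @param r Rate matrix (n x batch).
#' @param weights Optional precomputed effective weights.
#' @return List with \code{probs} (n_actions x batch softmax policy) and
#'   \code{value} (length-batch critic output).
#' @export
readout <- function(net, r, weights = NULL) {
  w <- if (is.null(weights)) effective_weights(net) else weights
  r <- as.matrix(r)
  logits <- w$W_a %*% r + net$b_a
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), `/`)
  value <- as.numeric(w$W_c %*% r) + net$b_c
  list(probs = probs, value = value, logits = logits)
}

#' Apply a computational lesion
#'
#' \code{"recurrent_removal"} zeroes the recurrent weight matrix, isolating
#' the feedforward pathway; \code{"clamp"} forces the listed neurons' rates
#' to zero at every step. The original parameters are untouched (the lesion
#' is a flag consulted by the forward model).
#'
#' @param net An \code{ei_network}.
#' @param type \code{"recurrent_removal"} or \code{"clamp"}.
#' @param neurons Integer indices for \code{"clamp"}.
#' @return Lesioned copy of the network.
#' @export
apply_lesion <- function(net, type = c("recurrent_removal", "clamp"),
                         neurons = NULL) {
  type <- match.arg(type)
  if (type == "clamp") {
    neurons <- as.integer(neurons)
    if (length(neurons) > 0 &&
        (min(neurons) < 1 || max(neurons) > net$cfg$n))
      stop("unknown neuron index in lesion set")
  }
  net$lesion <- list(type = type, neurons = neurons)
  net
}

#' Remove any lesion
#' @param net An \code{ei_network}.
#' @return Intact network.
#' @export
clear_lesion <- function(net) { net$lesion <- NULL; net }

#' Cell type of each neuron
#' @param net An \code{ei_network}.
#' @return Character vector "E"/"I" of length n.
#' @export
cell_types <- function(net) ifelse(net$dale_sign > 0, "E", "I")

#' Save a network checkpoint
#'
#' Parameters, Dale sign vector and configuration are serialized with
#' \code{saveRDS}; \code{export_network_json} writes the same content as
#' portable JSON text.
#'
#' @param net An \code{ei_network}.
#' @param path Output file path.
#' @export
save_checkpoint <- function(net, path) saveRDS(net, path)

#' Load a network checkpoint
#' @param path File written by \code{save_checkpoint}.
#' @return The \code{ei_network}.
#' @export
load_checkpoint <- function(path) readRDS(path)

#' @rdname save_checkpoint
#' @export
export_network_json <- function(net, path) {
  x <- list(cfg = unclass(net$cfg), dale_sign = net$dale_sign,
            W_rec = net$W_rec, W_in = net$W_in, W_a = net$W_a,
            W_c = net$W_c, b = net$b, b_a = net$b_a, b_c = net$b_c)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
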
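# shared fixture builders -------------------------------------------------

rand_array <- function(dims) array(rnorm(prod(dims)), dims)

# random multifrequency tensor + matching kernel for given settings
rand_case <- function(d = 2, alpha_in = 0.5, alpha_out = 0.5, k = 3,
                      c_in = 4, c_out = 4, high = rep(8, d), bias = TRUE,
                      transpose = FALSE) {
  split <- split_channels(c_in, alpha_in)
  x_h <- if (split[["high"]] > 0) rand_array(c(split[["high"]], high))
  x_l <- if (split[["low"]] > 0) rand_array(c(split[["low"]], high %/% 2L))
  kern <- octave_kernel(k, c_in, c_out, alpha_in, alpha_out, d = d, bias = bias,
                        transpose = transpose)
  if (bias) {
    if (!is.null(kern$bias$high)) kern$bias$high <- rnorm(length(kern$bias$high))
    if (!is.null(kern$bias$low)) kern$bias$low <- rnorm(length(kern$bias$low))
  }
  list(input = multifreq_tensor(x_h, x_l, alpha = alpha_in), kernel = kern)
}

max_branch_diff <- function(a, b) {
  dh <- if (is.null(a$high)) 0 else max(abs(a$high - b$high))
  dl <- if (is.null(a$low)) 0 else max(abs(a$low - b$low))
  max(dh, dl)
}

rel_tol_scale <- function(a) {
  m <- 0
  if (!is.null(a$high)) m <- max(m, max(abs(a$high)))
  if (!is.null(a$low)) m <- max(m, max(abs(a$low)))
  max(m, 1)
}

# tiny phantom-backed run config used by training smoke tests
tiny_run_config <- function(seed = 1, epochs = 5, alpha = 0.5, aux = 1,
                            levels = 2, n_train = 4, n_val = 2, shape = c(16, 16)) {
  run_config(
    network = ocunet_config(dims = 2, levels = levels, base_channels = 4,
                            alpha = alpha, convs_per_block = 1, aux_branches = aux),
    loss = list(weights = loss_weights(aux = rep(c(0.5, 0.25), length.out = aux))),
    data = list(kind = "phantom", n_train = n_train, n_val = n_val,
                spec = phantom_spec(shape = shape, n_lesions = c(1, 2),
                                    lesion_radius = c(2, 4),
                                    background_smoothness = c(4, 8))),
    training = list(epochs = epochs, batch_size = 4, seed = seed, val_every = 5))
}
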
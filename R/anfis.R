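#' Generalized bell membership function
#'
#' `mu(x) = 1 / (1 + |(x - c)/a|^(2b))`: a smooth bump equal to 1 at the
#' center `c`, exactly 0.5 at `c - a` and `c + a` for any shape exponent
#' `b`, with tails that fall off faster for larger `b`.
#'
#' @param x Numeric vector of input values.
#' @param a Width parameter, `> 0` (half-width at half-maximum).
#' @param b Shape exponent, `> 0`.
#' @param c Center, in the units of `x`.
#' @return Membership values in `(0, 1]`.
#' @export
bell_mf <- function(x, a, b, c) {
  if (!is.finite(a) || a <= 0) stop("bell MF width 'a' must be > 0")
  if (!is.finite(b) || b <= 0) stop("bell MF exponent 'b' must be > 0")
  1 / (1 + abs((x - c) / a)^(2 * b))
}

#' Number of free parameters of a grid-partition model
#'
#' Each of the `n` inputs carries `m` bell functions with 3 premise
#' parameters, and each of the `m^n` grid rules carries `n` linear
#' coefficients plus a constant: `D = 3 m n + m^n (n + 1)`.
#'
#' @param n_inputs Number of inputs.
#' @param m Membership functions per input.
#' @return Integer parameter count.
#' @export
anfis_dim <- function(n_inputs, m) {
  3L * m * n_inputs + m^n_inputs * (n_inputs + 1L)
}

#' Build a grid-partition Sugeno fuzzy model
#'
#' Constructs a first-order Sugeno system with `m` generalized bell
#' membership functions per input and one rule per cell of the full
#' `m^n` grid. Membership centers are equally spaced over each input's
#' range, widths are set so adjacent bells cross near membership 0.5
#' (`a = range / (2(m - 1))`), shape exponents start at 2, and all rule
#' consequents start at zero. Rules are enumerated in odometer order over
#' the membership indices with the **last input varying fastest**, which
#' fixes the layout of the flat parameter vector.
#'
#' @param input_ranges Numeric matrix with one row per input and columns
#'   `(min, max)`; row names become input names.
#' @param m Membership functions per input (default 2; must be >= 2).
#' @param input_names Optional character vector of input names.
#' @return An object of class `anfis` with elements `n_inputs`, `m`,
#'   `a`, `b`, `c` (each an `m x n` matrix of premise parameters),
#'   `rule_mf` (`m^n x n` integer matrix of membership indices),
#'   `coeffs` (`m^n x (n+1)` consequent matrix, intercept last),
#'   `input_names` and `input_ranges`.
#' @export
build_grid_model <- function(input_ranges, m = 2L,
                             input_names = rownames(input_ranges)) {
  input_ranges <- as.matrix(input_ranges)
  if (ncol(input_ranges) != 2L)
    stop("'input_ranges' must have two columns (min, max)")
  n <- nrow(input_ranges)
  if (m < 2L) stop("at least 2 membership functions per input are required")
  if (any(input_ranges[, 2L] <= input_ranges[, 1L]))
    stop("degenerate input range: min must be < max for every input")
  if (is.null(input_names)) input_names <- paste0("x", seq_len(n))

  a <- b <- cc <- matrix(0, m, n)
  for (j in seq_len(n)) {
    lo <- input_ranges[j, 1L]; hi <- input_ranges[j, 2L]
    cc[, j] <- seq(lo, hi, length.out = m)
    a[, j] <- (hi - lo) / (2 * (m - 1))
    b[, j] <- 2
  }
  # odometer over MF indices, last input fastest
  rule_mf <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))[, n:1,
                                                              drop = FALSE]
  dimnames(rule_mf) <- list(NULL, input_names)
  storage.mode(rule_mf) <- "integer"
  coeffs <- matrix(0, nrow(rule_mf), n + 1L)
  colnames(coeffs) <- c(input_names, "intercept")
  structure(list(n_inputs = n, m = as.integer(m), a = a, b = b, c = cc,
                 rule_mf = rule_mf, coeffs = coeffs,
                 input_names = input_names, input_ranges = input_ranges),
            class = "anfis")
}

#' @export
print.anfis <- function(x, ...) {
  cat("<anfis> first-order Sugeno model:", x$n_inputs, "inputs,",
      x$m, "bell MFs each,", nrow(x$rule_mf), "rules,",
      anfis_dim(x$n_inputs, x$m), "parameters\n")
  invisible(x)
}

# Per-input membership matrices for a batch of inputs.
# Returns a list (one per input) of N x m matrices.
membership_matrices <- function(model, X) {
  lapply(seq_len(model$n_inputs), function(j) {
    v <- vapply(seq_len(model$m),
                function(i) bell_mf(X[, j], model$a[i, j], model$b[i, j],
                                    model$c[i, j]),
                numeric(nrow(X)))
    matrix(v, nrow = nrow(X), ncol = model$m)   # keep matrix shape at N = 1
  })
}

#' Rule firing strengths for one input vector
#'
#' The firing strength of a rule is the product of its membership values,
#' one per input (the Pi nodes of the network's second layer).
#'
#' @param model An `anfis` model.
#' @param x Numeric vector of length `n_inputs`.
#' @return Numeric vector of per-rule strengths, all `>= 0`.
#' @export
firing_strengths <- function(model, x) {
  if (length(x) != model$n_inputs)
    stop("input has length ", length(x), ", expected ", model$n_inputs)
  X <- matrix(as.numeric(x), nrow = 1L)
  M <- membership_matrices(model, X)
  w <- rep(1, nrow(model$rule_mf))
  for (j in seq_len(model$n_inputs))
    w <- w * M[[j]][1L, model$rule_mf[, j]]
  w
}

#' Normalize rule firing strengths
#'
#' Divides each strength by the total so the normalized strengths sum to 1
#' (the N nodes of the third layer).
#'
#' @param strengths Non-negative numeric vector.
#' @return Vector proportional to `strengths` summing to 1.
#' @export
normalize_strengths <- function(strengths) {
  if (any(strengths < 0)) stop("firing strengths must be non-negative")
  s <- sum(strengths)
  if (s == 0)
    stop("all firing strengths are zero: input lies outside the support ",
         "of every rule")
  strengths / s
}

#' Single forward pass with layer-by-layer trace
#'
#' Evaluates the five-layer network on one input vector: memberships
#' (layer 1), rule firing strengths as membership products (layer 2),
#' normalized strengths (layer 3), weighted first-order rule outputs
#' (layer 4) and their sum (layer 5).
#'
#' @param model An `anfis` model.
#' @param x Numeric vector of length `n_inputs`.
#' @return List with `output` (scalar) and `trace`, a list holding
#'   `memberships` (`m x n` matrix), `firing_strengths`,
#'   `normalized_strengths` and `rule_outputs` (per-rule vectors).
#' @export
anfis_forward <- function(model, x) {
  w <- firing_strengths(model, x)
  wn <- normalize_strengths(w)
  f <- as.numeric(model$coeffs %*% c(as.numeric(x), 1))
  rule_out <- wn * f
  X <- matrix(as.numeric(x), nrow = 1L)
  M <- membership_matrices(model, X)
  memb <- vapply(M, function(mj) mj[1L, ], numeric(model$m))
  list(output = sum(rule_out),
       trace = list(memberships = memb, firing_strengths = w,
                    normalized_strengths = wn, rule_outputs = rule_out))
}

#' Batch forward evaluation
#'
#' Vectorized network output for a matrix of inputs; this is the hot path
#' used by training and prediction. Rows whose firing strengths all
#' underflow to zero yield `NA` (callers decide whether that is an error
#' or an infinite-fitness penalty).
#'
#' @param model An `anfis` model.
#' @param X Numeric matrix with `n_inputs` columns.
#' @return Numeric vector of outputs, one per row of `X`.
#' @export
anfis_evaluate <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_inputs)
    stop("input matrix has ", ncol(X), " columns, expected ", model$n_inputs)
  M <- membership_matrices(model, X)
  W <- matrix(1, nrow(X), nrow(model$rule_mf))
  for (j in seq_len(model$n_inputs))
    W <- W * M[[j]][, model$rule_mf[, j], drop = FALSE]
  s <- rowSums(W)
  f <- cbind(X, 1) %*% t(model$coeffs)
  out <- rowSums(W * f) / s
  out[s == 0] <- NA_real_
  out
}

#' Flatten model parameters to a vector
#'
#' Layout (fixing the search-space coordinates used by the optimizer):
#' first the premise block — for input `j = 1..n`, for membership
#' `i = 1..m`, the triple `(a, b, c)` — then the consequent block, one
#' rule at a time in rule order, each rule contributing its `n` linear
#' coefficients followed by its intercept.
#'
#' @param model An `anfis` model.
#' @return Numeric vector of length [anfis_dim()].
#' @export
params_to_vector <- function(model) {
  arr <- array(0, c(3L, model$m, model$n_inputs))
  arr[1L, , ] <- model$a
  arr[2L, , ] <- model$b
  arr[3L, , ] <- model$c
  c(as.vector(arr), as.vector(t(model$coeffs)))
}

#' Rebuild a model from a flat parameter vector
#'
#' Inverse of [params_to_vector()]: the template supplies structure
#' (inputs, membership count, rule base); the vector supplies parameter
#' values.
#'
#' @param v Numeric vector of length `anfis_dim(n, m)`.
#' @param template An `anfis` model with the target structure.
#' @return An `anfis` model.
#' @export
vector_to_params <- function(v, template) {
  n <- template$n_inputs; m <- template$m
  D <- anfis_dim(n, m)
  if (length(v) != D)
    stop("parameter vector has length ", length(v), ", expected ", D)
  np <- 3L * m * n
  arr <- array(v[seq_len(np)], c(3L, m, n))
  model <- template
  model$a <- matrix(arr[1L, , ], m, n)
  model$b <- matrix(arr[2L, , ], m, n)
  model$c <- matrix(arr[3L, , ], m, n)
  model$coeffs <- matrix(v[(np + 1L):D], nrow(template$rule_mf), n + 1L,
                         byrow = TRUE,
                         dimnames = dimnames(template$coeffs))
  model
}

#' Search-space bounds for the model parameters
#'
#' Keeps membership functions non-degenerate during optimization: widths
#' within a decade of their grid defaults, shape exponents in `[0.5, 5]`,
#' centers within a window 1.5 times the feature range (centered on its
#' midpoint). Consequents are unbounded; their initialization window is
#' `[-5, 5]` and serves to scale the velocity cap for those dimensions.
#'
#' @param model A freshly built grid model (its `a` values are the `a0`
#'   reference widths).
#' @return List with numeric vectors `lower`, `upper`, `init_lower`,
#'   `init_upper`, each of length [anfis_dim()].
#' @export
anfis_param_bounds <- function(model) {
  n <- model$n_inputs; m <- model$m
  lo_a <- 0.1 * model$a;  hi_a <- 10 * model$a
  lo_b <- matrix(0.5, m, n); hi_b <- matrix(5, m, n)
  mid <- (model$input_ranges[, 1L] + model$input_ranges[, 2L]) / 2
  half <- 0.75 * (model$input_ranges[, 2L] - model$input_ranges[, 1L])
  lo_c <- matrix(rep(mid - half, each = m), m, n)
  hi_c <- matrix(rep(mid + half, each = m), m, n)
  pack <- function(A, B, C) {
    arr <- array(0, c(3L, m, n))
    arr[1L, , ] <- A; arr[2L, , ] <- B; arr[3L, , ] <- C
    as.vector(arr)
  }
  nc <- nrow(model$rule_mf) * (n + 1L)
  list(lower      = c(pack(lo_a, lo_b, lo_c), rep(-Inf, nc)),
       upper      = c(pack(hi_a, hi_b, hi_c), rep(Inf, nc)),
       init_lower = c(pack(lo_a, lo_b, lo_c), rep(-5, nc)),
       init_upper = c(pack(hi_a, hi_b, hi_c), rep(5, nc)))
}

#' Serialize a model to structured text
#'
#' Writes a versioned JSON document carrying the full model (structure and
#' parameters) at full double precision, so [read_anfis()] reproduces the
#' model bit-exactly.
#'
#' @param model An `anfis` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_anfis <- function(model, path) {
  # doubles are written as %.17g strings: human-readable and exactly
  # round-trippable, which plain JSON number formatting is not
  chr <- function(x) {
    y <- sprintf("%.17g", x)
    dim(y) <- dim(x)
    y
  }
  doc <- list(format = "anfis-model", version = 1L,
              n_inputs = model$n_inputs, m = model$m,
              input_names = model$input_names,
              input_ranges = chr(unname(model$input_ranges)),
              a = chr(model$a), b = chr(model$b), c = chr(model$c),
              rule_mf = unname(model$rule_mf),
              coeffs = chr(unname(model$coeffs)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#' @param path File written by [write_anfis()].
#' @return An `anfis` model.
#' @export
read_anfis <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "anfis-model"))
    stop("not an anfis model file: ", path)
  num <- function(x) {
    y <- as.numeric(x)
    dim(y) <- dim(x)
    y
  }
  rule_mf <- matrix(as.integer(doc$rule_mf), nrow = nrow(doc$rule_mf),
                    dimnames = list(NULL, doc$input_names))
  coeffs <- num(doc$coeffs)
  dimnames(coeffs) <- list(NULL, c(doc$input_names, "intercept"))
  ranges <- num(doc$input_ranges)
  rownames(ranges) <- doc$input_names
  structure(list(n_inputs = as.integer(doc$n_inputs), m = as.integer(doc$m),
                 a = num(doc$a), b = num(doc$b), c = num(doc$c),
                 rule_mf = rule_mf, coeffs = coeffs,
                 input_names = doc$input_names, input_ranges = ranges),
            class = "anfis")
}
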
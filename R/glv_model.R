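#' Construct a generalized Lotka-Volterra model
#'
#' A gLV model couples n taxa through
#' \deqn{dx_i/dt = x_i (r_i + \sum_j \alpha_{ij} x_j)}
#' where `r_i` is the intrinsic per-capita growth rate of taxon i (units
#' 1/time) and `alpha_ij` the per-abundance effect of taxon j on taxon i's
#' growth rate (units 1/(abundance x time)). Positive `alpha_ij` is a
#' beneficial effect, negative inhibitory, zero no interaction.
#'
#' @param taxa Character vector of taxon names.
#' @param growth_rates Numeric vector `r`, one entry per taxon.
#' @param interactions Numeric n-by-n matrix `alpha`; entry `[i, j]` is the
#'   effect of taxon j on taxon i.
#' @param method_tag One of `"unconstrained"`, `"constrained"`,
#'   `"user_supplied"` recording how the parameters were obtained. A
#'   `"constrained"` model must satisfy `r >= 0` and `diag(alpha) <= 0`.
#' @return An object of class `glv_model`.
#' @examples
#' m <- glv_model(c("A", "B"), c(0.5, 0.3),
#'                matrix(c(-0.1, 0.01, 0.02, -0.2), 2, 2))
#' m
#' @export
glv_model <- function(taxa, growth_rates, interactions,
                      method_tag = c("user_supplied", "unconstrained", "constrained")) {
  method_tag <- match.arg(method_tag)
  taxa <- trimws(as.character(taxa))
  growth_rates <- as.numeric(growth_rates)
  interactions <- as.matrix(interactions)
  storage.mode(interactions) <- "double"
  n <- length(taxa)
  if (n == 0L) abort_validation("model needs at least one taxon")
  if (anyDuplicated(taxa)) abort_format("duplicate taxon names in model")
  if (length(growth_rates) != n) {
    abort_validation("growth_rates length does not match number of taxa")
  }
  if (!all(dim(interactions) == c(n, n))) {
    abort_validation(sprintf("interaction matrix must be %d x %d", n, n))
  }
  if (any(!is.finite(growth_rates)) || any(!is.finite(interactions))) {
    abort_validation("model parameters must all be finite")
  }
  if (method_tag == "constrained" &&
      (any(growth_rates < 0) || any(diag(interactions) > 0))) {
    abort_validation("constrained model requires r >= 0 and diag(alpha) <= 0")
  }
  dimnames(interactions) <- list(taxa, taxa)
  names(growth_rates) <- taxa
  structure(list(taxa = taxa, growth_rates = growth_rates,
                 interactions = interactions, method_tag = method_tag),
            class = "glv_model")
}

#' @export
print.glv_model <- function(x, ...) {
  cat(sprintf("gLV model: %d taxa (%s parameters)\n", length(x$taxa), x$method_tag))
  cat("  growth rates:\n")
  print(round(x$growth_rates, 4))
  cat("  interactions (row = affected taxon):\n")
  print(round(x$interactions, 4))
  invisible(x)
}

#' @export
coef.glv_model <- function(object, ...) {
  cbind(r = object$growth_rates, object$interactions)
}
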
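# Conditional misclassification probabilities.
#
# Empirical classification likelihoods P(predicted | true) come from a
# combined confusion matrix; Bayes' rule combines them with a prior to give
# the posterior probability of a true state given an observed
# classification. The sequence-case model asks: how likely is the present
# sample to be classified in set S given that n prior samples at the same
# location were all classified as b?
#
# The counted matrix can be read in either orientation (rows = predicted,
# the printed-table convention, or rows = true) because the source data are
# internally inconsistent about it; the orientation is an explicit argument,
# never guessed.

# P(predicted | true) matrix from a confusion matrix.
likelihood_matrix <- function(cm, orientation = c("rows_predicted",
                                                  "rows_true")) {
  orientation <- match.arg(orientation)
  m <- unclass(cm)
  if (orientation == "rows_predicted") m <- t(m)  # -> rows = true
  tot <- rowSums(m)
  if (any(tot == 0)) stop("a true class has no observations", call. = FALSE)
  sweep(m, 1, tot, "/")  # rows = true, cols = predicted
}

#' Empirical classification likelihood from a confusion matrix
#'
#' Probability that a sample of the given true class is classified into any
#' of `predicted_set`, estimated as the corresponding count fraction.
#'
#' @param cm A `tier_confusion`.
#' @param true_class True class label.
#' @param predicted_set Character vector of predicted class labels.
#' @param orientation `"rows_predicted"` (printed-table convention) or
#'   `"rows_true"`.
#' @return Probability in \[0, 1\].
#' @export
empirical_likelihood <- function(cm, true_class, predicted_set,
                                 orientation = "rows_predicted") {
  L <- likelihood_matrix(cm, orientation)
  stopifnot(true_class %in% rownames(L),
            all(predicted_set %in% colnames(L)))
  sum(L[true_class, predicted_set])
}

#' Bayes posterior probability
#'
#' `P(A|B) = P(B|A) P(A) / (P(B|A) P(A) + P(B|-A) (1 - P(A)))`.
#'
#' @param prior P(A).
#' @param likelihood P(B|A).
#' @param likelihood_complement P(B|-A).
#' @return P(A|B).
#' @export
bayes_posterior <- function(prior, likelihood, likelihood_complement) {
  stopifnot(prior >= 0, prior <= 1,
            likelihood >= 0, likelihood <= 1,
            likelihood_complement >= 0, likelihood_complement <= 1)
  marg <- likelihood * prior + likelihood_complement * (1 - prior)
  if (marg <= 0) stop("zero marginal probability P(B)", call. = FALSE)
  likelihood * prior / marg
}

#' Probability of a present classification given prior classifications
#'
#' Under the shared-true-class model: all samples at the location share one
#' unknown true class; the class prior is the empirical true-class marginal
#' of the confusion matrix; classifications are conditionally independent
#' given the true class, with the empirical likelihoods. Then
#' \deqn{P(present \in S \mid n prior = b) =
#'   \frac{\sum_t \pi_t L(b|t)^n \sum_{s \in S} L(s|t)}
#'        {\sum_t \pi_t L(b|t)^n}}
#' computed by total probability over the true classes.
#'
#' @param cm A `tier_confusion` (typically the combined matrix).
#' @param prior_predicted_class Class the prior samples were classified as.
#' @param n_prior Number of prior samples (>= 0; 0 gives the marginal).
#' @param present_predicted_set Set of classes for the present sample.
#' @param orientation Matrix orientation, see [empirical_likelihood()].
#' @param assumption Dependence model; only `"shared_true_class"` is
#'   defined.
#' @return List with `probability`, and `posterior_weights` (per-true-class
#'   posterior given the priors).
#' @export
sequence_case_probability <- function(cm, prior_predicted_class, n_prior,
                                      present_predicted_set,
                                      orientation = "rows_predicted",
                                      assumption = "shared_true_class") {
  assumption <- match.arg(assumption, "shared_true_class")
  stopifnot(n_prior >= 0)
  L <- likelihood_matrix(cm, orientation)
  m <- unclass(cm)
  if (orientation == "rows_predicted") m <- t(m)  # rows = true
  prior_t <- rowSums(m) / sum(m)
  w <- prior_t * L[, prior_predicted_class]^n_prior
  if (sum(w) <= 0) {
    stop("conditioning event has zero empirical probability", call. = FALSE)
  }
  w <- w / sum(w)
  p <- sum(w * rowSums(L[, present_predicted_set, drop = FALSE]))
  list(probability = p, posterior_weights = w)
}
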
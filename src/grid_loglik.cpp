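#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Numerically stable log of the logistic function.
static inline double log_sigmoid(double x) {
  if (x > 0.0) {
    return -std::log1p(std::exp(-x));
  }
  return x - std::log1p(std::exp(x));
}

// Log-likelihood of the observed choices at every node of the parameter
// grid. rwin (n_aw x T) and rloss (n_al x T) hold the belief entering each
// scored trial for every learning-rate grid value; choices are evaluated
// under P(A) = sigmoid(beta * (rwin + t - rloss)).
//
// Returns a vector laid out as a column-major array with dimensions
// (n_aw, n_al, n_beta, n_t).
// [[Rcpp::export]]
Rcpp::NumericVector grid_loglik_cpp(const arma::mat& rwin,
                                    const arma::mat& rloss,
                                    const arma::vec& beta,
                                    const arma::vec& tvec,
                                    const arma::ivec& chose_A) {
  const arma::uword n_aw = rwin.n_rows;
  const arma::uword n_al = rloss.n_rows;
  const arma::uword n_b = beta.n_elem;
  const arma::uword n_t = tvec.n_elem;
  const arma::uword T = rwin.n_cols;
  if (rloss.n_cols != T || chose_A.n_elem != T) {
    Rcpp::stop("rwin, rloss and chose_A must agree on the number of trials");
  }

  // sign s_i = +1 when A was chosen: log P(choice_i) = log_sigmoid(s_i * x)
  arma::vec sign(T);
  for (arma::uword i = 0; i < T; ++i) {
    sign(i) = chose_A(i) ? 1.0 : -1.0;
  }

  Rcpp::NumericVector out(n_aw * n_al * n_b * n_t);
  double* o = out.begin();

  for (arma::uword it = 0; it < n_t; ++it) {
    const double t = tvec(it);
    for (arma::uword ib = 0; ib < n_b; ++ib) {
      const double b = beta(ib);
      for (arma::uword al = 0; al < n_al; ++al) {
        const double* rl = rloss.colptr(0) + al; // stride n_al over columns
        for (arma::uword aw = 0; aw < n_aw; ++aw) {
          double ll = 0.0;
          for (arma::uword i = 0; i < T; ++i) {
            const double d = rwin(aw, i) + t - rloss(al, i);
            ll += log_sigmoid(sign(i) * b * d);
          }
          o[aw + n_aw * (al + n_al * (ib + n_b * it))] = ll;
        }
        (void)rl;
      }
    }
  }

  out.attr("dim") = Rcpp::IntegerVector::create(n_aw, n_al, n_b, n_t);
  return out;
}

// Belief trajectories for a vector of learning rates: row j holds the
// estimate entering each trial under alpha[j], starting at 0.5 and updated
// every trial from the realized outcome locations.
// [[Rcpp::export]]
arma::mat belief_paths_cpp(const arma::vec& alpha, const arma::ivec& outcome_on_A) {
  const arma::uword n_a = alpha.n_elem;
  const arma::uword T = outcome_on_A.n_elem;
  arma::mat r(n_a, T);
  arma::vec cur(n_a, arma::fill::value(0.5));
  for (arma::uword i = 0; i < T; ++i) {
    r.col(i) = cur;
    const double o = static_cast<double>(outcome_on_A(i));
    cur += alpha % (o - cur);
  }
  return r;
}
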
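#include <Rcpp.h>

// Draw, for each run, a uniform k-subset of positions carrying the outcome
// over stimulus A (partial Fisher-Yates on the run's indices), writing into
// on_A. Uses R's RNG so draws are reproducible under set.seed().
static void draw_exact(std::vector<int>& scratch, int* offsets,
                       const Rcpp::IntegerVector& lens,
                       const Rcpp::IntegerVector& ks, int* on_A) {
  int pos = 0;
  for (int j = 0; j < lens.size(); ++j) {
    const int len = lens[j];
    const int k = ks[j];
    for (int i = 0; i < len; ++i) {
      scratch[i] = i;
      on_A[pos + i] = 0;
    }
    for (int i = 0; i < k; ++i) {
      int pick = i + static_cast<int>(unif_rand() * (len - i));
      if (pick >= len) pick = len - 1; // guard against unif_rand() == 1.0
      std::swap(scratch[i], scratch[pick]);
      on_A[pos + scratch[i]] = 1;
    }
    pos += len;
  }
  (void)offsets;
}

// Rejection-sample a pair of exact-frequency realizations until the number
// of trials where win and loss co-locate equals `target` (target < 0 means
// unconstrained: accept the first draw). Returns an empty list if the
// attempt budget is exhausted.
// [[Rcpp::export]]
Rcpp::List realize_pair_cpp(Rcpp::IntegerVector lens_w, Rcpp::IntegerVector ks_w,
                            Rcpp::IntegerVector lens_l, Rcpp::IntegerVector ks_l,
                            int target, int max_attempts) {
  int n = 0;
  for (int j = 0; j < lens_w.size(); ++j) n += lens_w[j];
  int n_l = 0;
  for (int j = 0; j < lens_l.size(); ++j) n_l += lens_l[j];
  if (n != n_l) Rcpp::stop("trajectories disagree on trial count");

  Rcpp::IntegerVector w(n), l(n);
  std::vector<int> scratch(n);
  const int budget = target < 0 ? 1 : max_attempts;
  for (int attempt = 1; attempt <= budget; ++attempt) {
    draw_exact(scratch, nullptr, lens_w, ks_w, w.begin());
    draw_exact(scratch, nullptr, lens_l, ks_l, l.begin());
    int n_both = 0;
    for (int i = 0; i < n; ++i) n_both += (w[i] == l[i]);
    if (target < 0 || n_both == target) {
      return Rcpp::List::create(
        Rcpp::Named("win_on_A") = w,
        Rcpp::Named("loss_on_A") = l,
        Rcpp::Named("n_both") = n_both,
        Rcpp::Named("attempts") = attempt
      );
    }
  }
  return Rcpp::List::create();
}
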
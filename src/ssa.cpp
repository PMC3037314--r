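#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie (direct method) for the N-cell quorum-sensing network:
//   M0_i <-> M1_i          (beta on / alpha off, telegraph mRNA)
//   M1_i -> M1_i + A_i     (k_plus, one channel per reporter)
//   A_i  -> 0              (k_minus)
//   A_i  -> A_ext          (D efflux)
//   A_ext -> A_i           (r*D influx; lumped over cells as N*r*D*A_ext
//                           with a uniform destination draw, which has the
//                           identical master equation)
//   A_ext -> 0             (k_minus)
// With dual = 2 reporters, reactions 2-5 are doubled: both reporters are
// synthesised from the same M_i and use separate external pools.
//
// Counts are stored as doubles (exact for integers far below 2^53).
// Stationary statistics are exact time-weighted integrals of the
// piecewise-constant trajectory over (t_burn, t_end]; no grid sampling.

namespace {

// index of the k-th cell (0-based) whose M equals m
int nth_cell_with_state(const std::vector<int>& M, int m, int k) {
  int seen = 0;
  for (int i = 0; i < (int)M.size(); ++i) {
    if (M[i] == m) {
      if (seen == k) return i;
      ++seen;
    }
  }
  return (int)M.size() - 1; // unreachable for valid k
}

// cell drawn with probability A[i]/sum(A)
int cell_weighted(const std::vector<double>& A, double target) {
  double cum = 0.0;
  int last_pos = -1;
  for (int i = 0; i < (int)A.size(); ++i) {
    if (A[i] > 0) last_pos = i;
    cum += A[i];
    if (target < cum) return i;
  }
  return last_pos; // guard against round-off fallthrough
}

} // namespace

// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(double alpha, double beta, double k_plus, double k_minus,
              double D, double r, int N, int n_rep,
              IntegerVector M0, NumericMatrix A0, NumericVector Aext0,
              double t_burn, double t_end,
              double thin_dt, int thin_cell, double max_events) {
  if (n_rep < 1 || n_rep > 2) stop("n_rep must be 1 or 2");
  if (M0.size() != N || A0.nrow() != N || A0.ncol() != n_rep ||
      Aext0.size() != n_rep)
    stop("initial state dimensions do not match N / n_rep");

  std::vector<int> M(M0.begin(), M0.end());
  std::vector< std::vector<double> > A(n_rep, std::vector<double>(N));
  std::vector<double> Aext(n_rep);
  for (int j = 0; j < n_rep; ++j) {
    Aext[j] = Aext0[j];
    for (int i = 0; i < N; ++i) A[j][i] = A0(i, j);
  }

  // running sums maintained incrementally
  int SM = 0;
  for (int i = 0; i < N; ++i) SM += M[i];
  std::vector<double> SA(n_rep, 0.0), S2(n_rep, 0.0);
  double C12 = 0.0; // sum_i A1_i * A2_i (dual only)
  for (int j = 0; j < n_rep; ++j)
    for (int i = 0; i < N; ++i) {
      SA[j] += A[j][i];
      S2[j] += A[j][i] * A[j][i];
    }
  if (n_rep == 2)
    for (int i = 0; i < N; ++i) C12 += A[0][i] * A[1][i];

  // time-weighted accumulators over (t_burn, t_end]
  double Tacc = 0.0, accM = 0.0, accPair = 0.0, accCross = 0.0, accDiff2 = 0.0;
  std::vector<double> accA(n_rep, 0.0), accA2(n_rep, 0.0), accExt(n_rep, 0.0);

  const bool do_thin = R_finite(thin_dt) && thin_dt > 0;
  std::vector<double> thin_t, thin_M, thin_Aext;
  std::vector< std::vector<double> > thin_A(n_rep);
  double t_thin = t_burn;

  const double infl_coef = (double)N * r * D;
  double t = 0.0, n_events = 0.0;
  bool absorbed = false;

  while (t < t_end) {
    double a_on  = beta * (N - SM);
    double a_off = alpha * SM;
    double atot = a_on + a_off;
    double a_syn[2], a_deg[2], a_eff[2], a_in[2], a_ext[2];
    for (int j = 0; j < n_rep; ++j) {
      a_syn[j] = k_plus * SM;
      a_deg[j] = k_minus * SA[j];
      a_eff[j] = D * SA[j];
      a_in[j]  = infl_coef * Aext[j];
      a_ext[j] = k_minus * Aext[j];
      atot += a_syn[j] + a_deg[j] + a_eff[j] + a_in[j] + a_ext[j];
    }

    double dt = (atot > 0) ? R::exp_rand() / atot : (t_end - t) + 1.0;
    double t_next = t + dt;

    // accumulate stationary window overlap of [t, t_next)
    double lo = (t > t_burn) ? t : t_burn;
    double hi = (t_next < t_end) ? t_next : t_end;
    if (hi > lo) {
      double w = hi - lo;
      Tacc += w;
      accM += w * SM;
      for (int j = 0; j < n_rep; ++j) {
        accA[j]  += w * SA[j];
        accA2[j] += w * S2[j];
        accExt[j] += w * Aext[j];
      }
      accPair += w * (SA[0] * SA[0] - S2[0]);
      if (n_rep == 2) {
        accCross += w * C12;
        accDiff2 += w * (S2[0] + S2[1] - 2.0 * C12);
      }
    }
    if (do_thin) {
      while (t_thin < t_next && t_thin <= t_end) {
        thin_t.push_back(t_thin);
        thin_M.push_back(M[thin_cell]);
        thin_Aext.push_back(Aext[0]);
        for (int j = 0; j < n_rep; ++j) thin_A[j].push_back(A[j][thin_cell]);
        t_thin += thin_dt;
      }
    }

    if (atot <= 0) { absorbed = true; t = t_end; break; }
    if (t_next >= t_end) { t = t_end; break; }
    t = t_next;

    // select and fire
    double u = unif_rand() * atot;
    if (u < a_on) {
      int k = (int)(unif_rand() * (N - SM));
      if (k >= N - SM) k = N - SM - 1;
      M[nth_cell_with_state(M, 0, k)] = 1;
      ++SM;
    } else if ((u -= a_on) < a_off) {
      int k = (int)(unif_rand() * SM);
      if (k >= SM) k = SM - 1;
      M[nth_cell_with_state(M, 1, k)] = 0;
      --SM;
    } else {
      u -= a_off;
      int j = 0;
      for (;;) {
        if (u < a_syn[j]) {
          int k = (int)(unif_rand() * SM);
          if (k >= SM) k = SM - 1;
          int i = nth_cell_with_state(M, 1, k);
          double old = A[j][i];
          A[j][i] += 1.0; SA[j] += 1.0; S2[j] += 2.0 * old + 1.0;
          if (n_rep == 2) C12 += A[1 - j][i];
          break;
        }
        u -= a_syn[j];
        if (u < a_deg[j]) {
          int i = cell_weighted(A[j], u / k_minus);
          double old = A[j][i];
          A[j][i] -= 1.0; SA[j] -= 1.0; S2[j] += -2.0 * old + 1.0;
          if (n_rep == 2) C12 -= A[1 - j][i];
          break;
        }
        u -= a_deg[j];
        if (u < a_eff[j]) {
          int i = cell_weighted(A[j], u / D);
          double old = A[j][i];
          A[j][i] -= 1.0; SA[j] -= 1.0; S2[j] += -2.0 * old + 1.0;
          if (n_rep == 2) C12 -= A[1 - j][i];
          Aext[j] += 1.0;
          break;
        }
        u -= a_eff[j];
        if (u < a_in[j]) {
          int i = (int)(unif_rand() * N);
          if (i >= N) i = N - 1;
          double old = A[j][i];
          A[j][i] += 1.0; SA[j] += 1.0; S2[j] += 2.0 * old + 1.0;
          if (n_rep == 2) C12 += A[1 - j][i];
          Aext[j] -= 1.0;
          break;
        }
        u -= a_in[j];
        if (u < a_ext[j] || j == n_rep - 1) {
          Aext[j] -= 1.0;
          break;
        }
        u -= a_ext[j];
        ++j;
      }
    }

    n_events += 1.0;
    if (n_events > max_events)
      stop("event budget exceeded (%.0f events); reduce t_end or D", max_events);
    if (((long long)n_events) % 4194304 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix A_final(N, n_rep);
  for (int j = 0; j < n_rep; ++j)
    for (int i = 0; i < N; ++i) A_final(i, j) = A[j][i];

  List thin = R_NilValue;
  if (do_thin) {
    List cols = List::create(_["t"] = wrap(thin_t), _["M"] = wrap(thin_M),
                             _["A1"] = wrap(thin_A[0]),
                             _["Aext"] = wrap(thin_Aext));
    if (n_rep == 2) cols["A2"] = wrap(thin_A[1]);
    thin = cols;
  }

  return List::create(
    _["T"] = Tacc, _["accA"] = wrap(accA), _["accA2"] = wrap(accA2),
    _["accPair"] = accPair, _["accCross"] = accCross, _["accDiff2"] = accDiff2,
    _["accM"] = accM, _["accExt"] = wrap(accExt),
    _["t_final"] = t, _["M_final"] = wrap(M), _["A_final"] = A_final,
    _["Aext_final"] = wrap(Aext), _["n_events"] = n_events,
    _["absorbed"] = absorbed, _["thin"] = thin);
}
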
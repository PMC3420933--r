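#include <Rcpp.h>
using namespace Rcpp;

// Stochastic kernel for the recruitment / noise / replication dynamics.
//
// Uses R's RNG (unif_rand) with a draw sequence that exactly mirrors the
// pure-R reference stepper (step_recruitment, step_noise, replicate_state),
// so a run is reproducible from set.seed() and bit-identical between the
// two implementations:
//   per iteration: u(substrate), u(recruiter among the other N-1),
//                  [u(choice) only when two reactions apply],
//                  u(noise gate), [u(nucleosome), u(neighbour) when fired]
//   per replication: one u per nucleosome.

// reaction table; must match reaction_table() on the R side
static const int RXN_SOURCE[8] = {1, 2, 3, 0, 0, 3, 2, 1};
static const int RXN_TARGET[8] = {0, 0, 2, 2, 1, 1, 3, 3};

// [[Rcpp::export(name = ".sim_run_cpp")]]
IntegerMatrix sim_run_cpp(IntegerVector slots, int E1, int E2, int Rtype,
                          int N, int attempts, double alpha,
                          int gens, int repeats,
                          bool replication, double replace_prob) {
  // applicability lookup: for recruiter q and substrate s, the 0..2 target
  // types, ordered by reaction id (ties between two applicable reactions
  // are broken by a fair coin)
  int cnt[4][4];
  int tg1[4][4];
  int tg2[4][4];
  for (int q = 0; q < 4; ++q)
    for (int s = 0; s < 4; ++s) { cnt[q][s] = 0; tg1[q][s] = -1; tg2[q][s] = -1; }
  for (int r = 0; r < 8; ++r) {
    if (slots[r] == NA_INTEGER) continue;
    int q = slots[r];
    int s = RXN_SOURCE[r];
    if (cnt[q][s] == 0) tg1[q][s] = RXN_TARGET[r];
    else tg2[q][s] = RXN_TARGET[r];
    cnt[q][s]++;
  }
  const int nb1[4] = {1, 0, 3, 2}; // flip position 1 (t xor 1)
  const int nb2[4] = {2, 3, 0, 1}; // flip position 2 (t xor 2)

  const int n_runs = 2 * repeats;
  const long T = (long)attempts * N;
  IntegerMatrix out(n_runs * gens, 5); // run, init, gen, nE1, nE2
  std::vector<int> state(N);

  int row = 0;
  for (int run = 0; run < n_runs; ++run) {
    const int init = (run % 2 == 0) ? E1 : E2;
    std::fill(state.begin(), state.end(), init);
    for (int g = 1; g <= gens; ++g) {
      for (long it = 0; it < T; ++it) {
        // recruitment attempt
        int n1 = (int)(unif_rand() * N);
        if (n1 == N) n1 = N - 1;
        int j = (int)(unif_rand() * (N - 1));
        if (j == N - 1) j = N - 2;
        int n2 = j + (j >= n1 ? 1 : 0);
        int s = state[n1];
        int q = state[n2];
        int c = cnt[q][s];
        if (c == 1) {
          state[n1] = tg1[q][s];
        } else if (c == 2) {
          state[n1] = (unif_rand() < 0.5) ? tg1[q][s] : tg2[q][s];
        }
        // noise
        if (unif_rand() < alpha) {
          int k = (int)(unif_rand() * N);
          if (k == N) k = N - 1;
          state[k] = (unif_rand() < 0.5) ? nb1[state[k]] : nb2[state[k]];
        }
      }
      // record just before replication
      int nE1 = 0, nE2 = 0;
      for (int i = 0; i < N; ++i) {
        if (state[i] == E1) ++nE1;
        else if (state[i] == E2) ++nE2;
      }
      out(row, 0) = run + 1;
      out(row, 1) = init;
      out(row, 2) = g;
      out(row, 3) = nE1;
      out(row, 4) = nE2;
      ++row;
      if (replication) {
        for (int i = 0; i < N; ++i) {
          if (unif_rand() < replace_prob) state[i] = Rtype;
        }
      }
    }
  }
  return out;
}
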
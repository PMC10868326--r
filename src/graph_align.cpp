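#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Exact fitting alignment of a read against a variant DAG under unit edit
// costs: the read is aligned end-to-end, leading/trailing graph characters
// are free (the graph locus extends beyond the read). Nodes are single
// characters (code 0 = epsilon junction / empty-branch marker) listed in
// topological order with flattened predecessor lists.
//
// Returns the optimal cost and, for each requested branch-end node, the
// optimal cost over alignments whose graph path passes through that node
// (used for per-allele forced costs and hence observation weights).
// [[Rcpp::export]]
List graph_align_cpp(IntegerVector nodeChar, IntegerVector predPtr,
                     IntegerVector predIdx, IntegerVector read,
                     IntegerVector branchEnd) {
  const int N = nodeChar.size();
  const int m = read.size();
  const int W = m + 1;
  const int INF = INT_MAX / 4;

  std::vector<int> F((size_t)N * W, INF);
  // forward: F[v][j] = min cost, graph consumed through v, read prefix j;
  // F[v][0] = 0 everywhere makes leading graph deletions free.
  for (int v = 0; v < N; ++v) {
    int *Fv = &F[(size_t)v * W];
    const int c = nodeChar[v];
    if (c != 0 && predPtr[v + 1] - predPtr[v] == 1) {
      // fast path: linear chain character node
      const int *Fp = &F[(size_t)predIdx[predPtr[v]] * W];
      Fv[0] = 0;
      for (int j = 1; j <= m; ++j) {
        int best = Fp[j - 1] + ((c == read[j - 1]) ? 0 : 1);
        if (Fp[j] + 1 < best) best = Fp[j] + 1;
        if (Fv[j - 1] + 1 < best) best = Fv[j - 1] + 1;
        Fv[j] = best;
      }
      continue;
    }
    for (int j = 0; j <= m; ++j) {
      int best = (j == 0) ? 0 : INF;
      if (j > 0 && Fv[j - 1] + 1 < best) best = Fv[j - 1] + 1; // insertion
      for (int p = predPtr[v]; p < predPtr[v + 1]; ++p) {
        const int *Fp = &F[(size_t)predIdx[p] * W];
        if (c == 0) {                       // epsilon: free pass-through
          if (Fp[j] < best) best = Fp[j];
        } else {
          if (Fp[j] + 1 < best) best = Fp[j] + 1;           // delete v
          if (j > 0) {
            int sub = Fp[j - 1] + ((c == read[j - 1]) ? 0 : 1);
            if (sub < best) best = sub;
          }
        }
      }
      Fv[j] = best;
    }
  }

  // successor lists
  std::vector<int> succPtr(N + 1, 0), succIdx(predIdx.size());
  for (int v = 0; v < N; ++v)
    for (int p = predPtr[v]; p < predPtr[v + 1]; ++p) succPtr[predIdx[p] + 1]++;
  for (int v = 0; v < N; ++v) succPtr[v + 1] += succPtr[v];
  {
    std::vector<int> fill(succPtr.begin(), succPtr.end() - 1);
    for (int v = 0; v < N; ++v)
      for (int p = predPtr[v]; p < predPtr[v + 1]; ++p)
        succIdx[fill[predIdx[p]]++] = v;
  }

  // backward: B[v][j] = min cost to consume read[j..m) in the graph
  // strictly after v, stopping anywhere (trailing deletions free).
  std::vector<int> B((size_t)N * W, INF);
  for (int v = N - 1; v >= 0; --v) {
    int *Bv = &B[(size_t)v * W];
    Bv[m] = 0;
    if (succPtr[v + 1] - succPtr[v] == 1 && nodeChar[succIdx[succPtr[v]]] != 0) {
      // fast path: linear chain into a character node
      const int w = succIdx[succPtr[v]];
      const int *Bw = &B[(size_t)w * W];
      const int cw = nodeChar[w];
      for (int j = m - 1; j >= 0; --j) {
        int best = Bw[j + 1] + ((cw == read[j]) ? 0 : 1);
        if (Bw[j] + 1 < best) best = Bw[j] + 1;
        if (Bv[j + 1] + 1 < best) best = Bv[j + 1] + 1;
        Bv[j] = best;
      }
      continue;
    }
    for (int j = m - 1; j >= 0; --j) {
      int best = Bv[j + 1] + 1; // insertion of read[j]
      for (int s = succPtr[v]; s < succPtr[v + 1]; ++s) {
        const int w = succIdx[s];
        const int *Bw = &B[(size_t)w * W];
        const int cw = nodeChar[w];
        if (cw == 0) {
          if (Bw[j] < best) best = Bw[j];
        } else {
          if (Bw[j] + 1 < best) best = Bw[j] + 1;           // delete w
          int sub = Bw[j + 1] + ((cw == read[j]) ? 0 : 1);
          if (sub < best) best = sub;
        }
      }
      Bv[j] = best;
    }
  }

  int bestCost = INF;
  for (int v = 0; v < N; ++v)
    if (F[(size_t)v * W + m] < bestCost) bestCost = F[(size_t)v * W + m];
  if (N == 0) bestCost = m; // degenerate empty graph: all insertions

  const int nb = branchEnd.size();
  IntegerVector forced(nb);
  for (int b = 0; b < nb; ++b) {
    const int v = branchEnd[b];
    const int *Fv = &F[(size_t)v * W];
    const int *Bv = &B[(size_t)v * W];
    int fc = INF;
    for (int j = 0; j <= m; ++j) {
      long s = (long)Fv[j] + (long)Bv[j];
      if (s < fc) fc = (int)s;
    }
    forced[b] = fc;
  }
  return List::create(Named("cost") = bestCost, Named("forced") = forced);
}
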
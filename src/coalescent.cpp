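// Structured coalescent for K demes with piecewise-constant demography.
//
// Time runs backwards in generations. Each epoch has per-deme diploid sizes,
// a backward migration-rate matrix (per lineage per generation), and a deme
// relabelling applied on entry (used to merge daughter demes into ancestors).
// Mutations follow the infinite-sites model: Poisson on total branch length,
// placed uniformly on branches, positions uniform on (0, 1) relative to the
// locus. No intra-locus recombination.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Edge {
  std::vector<int> desc;  // 0-based haplotype indices below this branch
  double len;             // branch length in generations
};

}  // namespace

// [[Rcpp::export(name = ".sim_locus_cpp")]]
List sim_locus_cpp(IntegerVector n_per_deme,
                   NumericVector epoch_end,
                   NumericMatrix Nsize,
                   List mig,
                   IntegerMatrix remap,
                   double mu_locus) {
  const int D = n_per_deme.size();
  const int E = epoch_end.size();
  if (Nsize.nrow() != E || Nsize.ncol() != D)
    stop("Nsize must be n_epochs x n_demes");
  if (remap.nrow() != E || remap.ncol() != D)
    stop("remap must be n_epochs x n_demes");
  if (!(epoch_end[E - 1] == R_PosInf))
    stop("last epoch must be unbounded");

  int n_total = 0;
  for (int d = 0; d < D; ++d) n_total += n_per_deme[d];
  if (n_total < 2) stop("need at least two haplotypes");

  // active lineages
  std::vector<int> deme;
  std::vector<double> birth;
  std::vector<std::vector<int> > desc;
  deme.reserve(2 * n_total);
  int hap = 0;
  for (int d = 0; d < D; ++d) {
    for (int i = 0; i < n_per_deme[d]; ++i) {
      deme.push_back(d);
      birth.push_back(0.0);
      desc.push_back(std::vector<int>(1, hap++));
    }
  }

  std::vector<Edge> edges;
  edges.reserve(4 * n_total);

  double t = 0.0;
  int e = 0;
  NumericMatrix m = as<NumericMatrix>(mig[0]);
  long long n_events = 0;
  const long long max_events = 50000000LL;

  std::vector<double> coal_rate(D), mig_out(D);
  std::vector<int> k(D);

  while ((int)deme.size() > 1) {
    if (++n_events > max_events) stop("event limit exceeded; check parameters");

    std::fill(k.begin(), k.end(), 0);
    for (size_t i = 0; i < deme.size(); ++i) k[deme[i]]++;

    double total = 0.0;
    for (int d = 0; d < D; ++d) {
      double N = Nsize(e, d);
      if (k[d] > 1) {
        if (!(N > 0)) stop("lineages present in a deme with size 0");
        coal_rate[d] = k[d] * (k[d] - 1) / 2.0 / (2.0 * N);
      } else {
        coal_rate[d] = 0.0;
      }
      double mo = 0.0;
      if (k[d] > 0)
        for (int j = 0; j < D; ++j)
          if (j != d) mo += m(d, j);
      mig_out[d] = k[d] * mo;
      total += coal_rate[d] + mig_out[d];
    }

    if (total <= 0.0) {
      if (epoch_end[e] == R_PosInf)
        stop("no coalescence possible: isolated lineages in final epoch");
      t = epoch_end[e];
    } else {
      double dt = R::rexp(1.0 / total);
      if (t + dt >= epoch_end[e]) {
        t = epoch_end[e];
      } else {
        t += dt;
        double u = R::runif(0.0, total);
        int d = 0;
        bool done = false;
        for (d = 0; d < D && !done; ++d) {
          if (u < coal_rate[d]) {
            // coalescence of two uniform lineages in deme d
            int a = (int)std::floor(R::runif(0.0, k[d]));
            int b = (int)std::floor(R::runif(0.0, k[d] - 1));
            if (a >= k[d]) a = k[d] - 1;
            if (b >= k[d] - 1) b = k[d] - 2 >= 0 ? k[d] - 2 : 0;
            if (b >= a) b += 1;
            // map deme-local indices to lineage indices
            int ia = -1, ib = -1, seen = 0;
            for (size_t i = 0; i < deme.size(); ++i) {
              if (deme[i] == d) {
                if (seen == a) ia = (int)i;
                if (seen == b) ib = (int)i;
                ++seen;
              }
            }
            Edge ea; ea.desc = desc[ia]; ea.len = t - birth[ia];
            Edge eb; eb.desc = desc[ib]; eb.len = t - birth[ib];
            edges.push_back(ea);
            edges.push_back(eb);
            // merged lineage replaces ia; remove ib by swap with back
            desc[ia].insert(desc[ia].end(), desc[ib].begin(), desc[ib].end());
            birth[ia] = t;
            int last = (int)deme.size() - 1;
            deme[ib] = deme[last]; birth[ib] = birth[last];
            desc[ib].swap(desc[last]);
            deme.pop_back(); birth.pop_back(); desc.pop_back();
            done = true;
            break;
          }
          u -= coal_rate[d];
          if (u < mig_out[d]) {
            // a uniform lineage of deme d migrates; destination by rate
            int a = (int)std::floor(R::runif(0.0, k[d]));
            if (a >= k[d]) a = k[d] - 1;
            int ia = -1, seen = 0;
            for (size_t i = 0; i < deme.size(); ++i) {
              if (deme[i] == d) { if (seen == a) { ia = (int)i; break; } ++seen; }
            }
            double mo = mig_out[d] / k[d];
            double v = R::runif(0.0, mo);
            int dest = -1;
            for (int j = 0; j < D; ++j) {
              if (j == d) continue;
              if (v < m(d, j)) { dest = j; break; }
              v -= m(d, j);
            }
            if (dest < 0) {
              for (int j = D - 1; j >= 0; --j) if (j != d) { dest = j; break; }
            }
            deme[ia] = dest;
            done = true;
            break;
          }
          u -= mig_out[d];
        }
        if (!done) stop("internal error: event selection failed");
        continue;
      }
    }

    // reached epoch boundary: advance epoch, relabel demes
    if (e + 1 >= E) stop("internal error: ran past final epoch");
    ++e;
    m = as<NumericMatrix>(mig[e]);
    for (size_t i = 0; i < deme.size(); ++i) {
      int nd = remap(e, deme[i]) - 1;
      if (nd < 0 || nd >= D) stop("remap out of range");
      deme[i] = nd;
    }
  }

  // drop mutations on edges
  double total_len = 0.0;
  for (size_t i = 0; i < edges.size(); ++i) total_len += edges[i].len;
  int n_mut = (int)R::rpois(mu_locus * total_len);

  IntegerMatrix geno(n_total, n_mut);
  NumericVector pos(n_mut);
  if (n_mut > 0) {
    std::vector<double> cum(edges.size());
    double acc = 0.0;
    for (size_t i = 0; i < edges.size(); ++i) { acc += edges[i].len; cum[i] = acc; }
    for (int s = 0; s < n_mut; ++s) {
      double u = R::runif(0.0, total_len);
      size_t lo = 0, hi = edges.size() - 1;
      while (lo < hi) {
        size_t mid = (lo + hi) / 2;
        if (cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      const std::vector<int>& dd = edges[lo].desc;
      for (size_t j = 0; j < dd.size(); ++j) geno(dd[j], s) = 1;
      pos[s] = R::runif(0.0, 1.0);
    }
  }

  return List::create(_["geno"] = geno, _["pos"] = pos);
}
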
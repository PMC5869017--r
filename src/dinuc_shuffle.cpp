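#include <Rcpp.h>
using namespace Rcpp;

// Altschul-Erickson dinucleotide-preserving shuffle. A random last-exit
// edge per vertex must form an arborescence into the terminal base; any
// permutation of the remaining out-edges then yields a valid Eulerian walk
// with the original dinucleotide multiset. Uses R's RNG so results are
// reproducible under set.seed().
static std::string shuffle_one(const std::string& s) {
  const int n = s.size();
  if (n < 2) return s;
  std::vector<int> id(256, -1);
  std::vector<char> chars;
  std::vector<int> seq(n);
  for (int i = 0; i < n; ++i) {
    unsigned char c = s[i];
    if (id[c] < 0) { id[c] = chars.size(); chars.push_back(c); }
    seq[i] = id[c];
  }
  const int V = chars.size();
  if (V == 1) return s;
  std::vector< std::vector<int> > out(V);
  for (int i = 0; i + 1 < n; ++i) out[seq[i]].push_back(seq[i + 1]);
  const int s1 = seq[0], sn = seq[n - 1];

  std::vector<int> last(V, -1);
  bool ok = false;
  for (int tries = 0; tries < 100000 && !ok; ++tries) {
    for (int v = 0; v < V; ++v) {
      last[v] = (v != sn && !out[v].empty())
        ? out[v][(int)(unif_rand() * out[v].size())] : -1;
    }
    ok = true;
    for (int v = 0; v < V && ok; ++v) {
      if (v == sn || out[v].empty()) continue;
      int cur = v, steps = 0;
      while (cur != sn && steps <= V && last[cur] >= 0) { cur = last[cur]; ++steps; }
      if (cur != sn) ok = false;
    }
  }
  if (!ok) return s;  // unreachable for real sequences; defensive only

  std::vector< std::vector<int> > ordered(V);
  for (int v = 0; v < V; ++v) {
    std::vector<int> e = out[v];
    if (v != sn && !e.empty()) {
      for (size_t i = 0; i < e.size(); ++i) {
        if (e[i] == last[v]) { e.erase(e.begin() + i); break; }
      }
    }
    for (int i = (int)e.size() - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      std::swap(e[i], e[j]);
    }
    if (v != sn && !out[v].empty()) e.push_back(last[v]);
    ordered[v] = e;
  }

  std::string res(n, 'N');
  std::vector<size_t> ptr(V, 0);
  int cur = s1;
  res[0] = chars[cur];
  for (int i = 1; i < n; ++i) {
    cur = ordered[cur][ptr[cur]++];
    res[i] = chars[cur];
  }
  return res;
}

// [[Rcpp::export(name = ".dinuc_shuffle_one")]]
std::string dinuc_shuffle_one(std::string s) {
  return shuffle_one(s);
}

// [[Rcpp::export(name = ".dinuc_shuffle_many")]]
CharacterVector dinuc_shuffle_many(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = shuffle_one(as<std::string>(x[i]));
  }
  return out;
}
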
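// Event-driven simulation core.
//
// Semantics: input events are processed in ascending timestamp order. Within
// one timestamp, pending spikes are arbitrated per layer (linear or
// round-robin polling, edge detectors holding H-1 pending spikes per line)
// and delivered breadth-per-layer; spikes emitted during delivery are
// injected, strictly ordered after the triggering grant, into the next
// layer's pending set and (for recurrent layers) back into the same layer's
// pending set. The cascade runs to quiescence before time advances.
//
// Accumulator arithmetic is plain int: 0..63 with wrap-around on >= 64 and
// clamp to 0 on underflow, identical to the R-level neuron contract.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <climits>
using namespace Rcpp;

namespace {

struct Layer {
  int n_in, n;
  bool recurrent, scale;
  std::vector<int> fwd;  // n_in x n, column-major (src + n_in * dst)
  std::vector<int> lat;  // n x n, column-major, empty if not recurrent
};

// Order one batch of simultaneous fan-in addresses; returns grant order,
// updates last_grant, adds capacity losses to *lost.
std::vector<int> arbitrate_batch(std::vector<int>& batch, int H,
                                 bool round_robin, int& last_grant,
                                 long long* lost) {
  std::map<int, int> cnt;
  for (int a : batch) cnt[a]++;
  int cap = H - 1;
  std::vector<int> addr;
  std::vector<int> pend;
  for (auto& kv : cnt) {
    addr.push_back(kv.first);
    if (kv.second > cap) *lost += kv.second - cap;
    pend.push_back(std::min(kv.second, cap));
  }
  std::vector<int> order;
  long long remaining = 0;
  for (int p : pend) remaining += p;
  while (remaining > 0) {
    // one polling round over live addresses
    std::vector<size_t> live;
    for (size_t i = 0; i < addr.size(); ++i)
      if (pend[i] > 0) live.push_back(i);
    std::vector<size_t> round;
    if (round_robin) {
      for (size_t i : live) if (addr[i] > last_grant) round.push_back(i);
      for (size_t i : live) if (addr[i] <= last_grant) round.push_back(i);
    } else {
      round = live;
    }
    for (size_t i : round) {
      order.push_back(addr[i]);
      pend[i]--;
      remaining--;
      last_grant = addr[i];
    }
  }
  return order;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_sim(List layers_in, NumericVector ev_t, IntegerVector ev_addr,
                 double duration_ns, int H, bool round_robin,
                 double max_cascade_events) {
  const int L = layers_in.size();
  std::vector<Layer> layers(L);
  for (int l = 0; l < L; ++l) {
    List li = layers_in[l];
    Layer& ly = layers[l];
    ly.n_in = as<int>(li["n_in"]);
    ly.n = as<int>(li["n"]);
    ly.scale = as<bool>(li["scale"]);
    IntegerMatrix fw = li["forward"];
    ly.fwd.assign(fw.begin(), fw.end());
    ly.recurrent = !Rf_isNull(li["lateral"]);
    if (ly.recurrent) {
      IntegerMatrix lt = li["lateral"];
      ly.lat.assign(lt.begin(), lt.end());
    }
  }

  // sort input events by timestamp
  const int n_ev = ev_t.size();
  std::vector<int> idx(n_ev);
  for (int i = 0; i < n_ev; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return ev_t[a] < ev_t[b]; });

  std::vector<std::vector<int>> acc(L);
  for (int l = 0; l < L; ++l) acc[l].assign(layers[l].n, 0);
  std::vector<int> last_grant(L, -1);
  std::vector<long long> lost(L, 0);
  std::vector<std::vector<int>> pending(L);

  std::vector<double> sp_t;
  std::vector<int> sp_layer, sp_neuron;
  long long processed_total = 0;
  bool runaway = false;
  double runaway_t = 0;

  int i = 0;
  while (i < n_ev && !runaway) {
    double t = ev_t[idx[i]];
    if (t > duration_ns) break;
    for (int l = 0; l < L; ++l) pending[l].clear();
    while (i < n_ev && ev_t[idx[i]] == t) {
      pending[0].push_back(ev_addr[idx[i]]);
      ++i;
    }
    long long processed_here = 0;
    bool any = true;
    while (any && !runaway) {
      any = false;
      for (int l = 0; l < L; ++l) {
        if (pending[l].empty()) continue;
        any = true;
        std::vector<int> batch;
        batch.swap(pending[l]);
        Layer& ly = layers[l];
        std::vector<int> order =
            arbitrate_batch(batch, H, round_robin, last_grant[l], &lost[l]);
        for (int src : order) {
          if (++processed_here > (long long)max_cascade_events) {
            runaway = true;
            runaway_t = t;
            break;
          }
          const int n = ly.n;
          bool lateral_src = src >= ly.n_in;
          const std::vector<int>& W = lateral_src ? ly.lat : ly.fwd;
          int s0 = lateral_src ? src - ly.n_in : src;
          int mul = ly.scale ? 8 : 1;
          int n_src = lateral_src ? ly.n : ly.n_in;
          for (int j = 0; j < n; ++j) {
            int w = W[s0 + (size_t)n_src * j];
            if (w == 0) continue;
            int s = acc[l][j] + w * mul;
            if (s >= 64) {
              acc[l][j] = s - 64;
              sp_t.push_back(t);
              sp_layer.push_back(l + 1);
              sp_neuron.push_back(j);
              if (ly.recurrent) pending[l].push_back(ly.n_in + j);
              if (l + 1 < L) pending[l + 1].push_back(j);
            } else if (s < 0) {
              acc[l][j] = 0;
            } else {
              acc[l][j] = s;
            }
          }
        }
        if (runaway) break;
      }
    }
    processed_total += processed_here;
  }

  List acc_out(L);
  IntegerVector lost_out(L);
  for (int l = 0; l < L; ++l) {
    acc_out[l] = IntegerVector(acc[l].begin(), acc[l].end());
    lost_out[l] = (int)std::min<long long>(lost[l], INT_MAX);
  }
  return List::create(
      _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["spike_layer"] = IntegerVector(sp_layer.begin(), sp_layer.end()),
      _["spike_neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
      _["acc"] = acc_out, _["lost"] = lost_out,
      _["n_processed"] = (double)processed_total,
      _["runaway"] = runaway, _["runaway_t"] = runaway_t);
}
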
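#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Discrete-event engine for signal traffic on a directed network.
//
// Mechanics (see simulate_traffic() for the user-facing contract):
//  * exogenous generations: one network-wide Poisson process; source uniform
//    over nodes, destination uniform over the other N-1 nodes
//  * arrival at the destination removes the unit immediately (no queueing)
//  * single non-preemptive exponential server per node
//  * finite LIFO buffer of K slots: the newest unit always enters at the
//    front; on overflow the oldest queued unit (back of buffer) is ejected;
//    the unit in service is never ejected
//  * on completion the unit hops along one efferent edge chosen uniformly;
//    the arrival at the downstream node is processed before the next unit
//    at this node begins service
//
// All randomness is drawn from R's RNG (Mersenne-Twister under the default
// set.seed()), exponential variates by inverse transform -log(u)/rate.

namespace {

struct Event {
  double t;
  long seq;      // monotone insertion counter: ties resolved first-scheduled
  int type;      // 0 = generation, 1 = service completion
  int node;
  long unit;
};

struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

inline double rexp_inv(double rate) {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return -std::log(u) / rate;
}

// event-log record types
enum LogType { GENERATE = 0, ARRIVE = 1, DELIVER = 2, EJECT = 3,
               START_SERVICE = 4, COMPLETE = 5 };

struct Engine {
  int N;
  const std::vector<int>& offsets;   // CSR out-adjacency, length N+1
  const std::vector<int>& targets;   // length E, edge id = CSR position
  double lambda, mu, T, trans;
  int K;
  bool count_deliveries, record;

  std::priority_queue<Event, std::vector<Event>, EventCmp> pq;
  long seq = 0;

  std::vector<int> serving;               // unit id in service, -1 if idle
  std::vector<std::vector<long> > buf;    // [0]=back (oldest) ... end=front
  std::vector<int> nq;                    // current contents n_i
  std::vector<int> maxq;                  // max observed queue length
  std::vector<double> last_t;             // last accumulator update time
  std::vector<double> busy_int, cont_int; // post-transient integrals
  std::vector<long> arrivals;             // post-transient arrival counts
  std::vector<long> edge_count;           // post-transient traversals
  std::vector<int> dest;                  // per-unit destination

  long generated = 0, delivered = 0, ejected = 0;

  // optional logs
  std::vector<double> log_t;
  std::vector<int> log_type, log_node;
  std::vector<long> log_unit;
  std::vector<double> traj_t;
  std::vector<int> traj_node, traj_n;

  Engine(int N_, const std::vector<int>& off, const std::vector<int>& tgt,
         double lambda_, double mu_, int K_, double T_, double trans_,
         bool count_del, bool record_)
    : N(N_), offsets(off), targets(tgt), lambda(lambda_), mu(mu_),
      T(T_), trans(trans_), K(K_),
      count_deliveries(count_del), record(record_),
      serving(N_, -1), buf(N_), nq(N_, 0), maxq(N_, 0), last_t(N_, 0.0),
      busy_int(N_, 0.0), cont_int(N_, 0.0), arrivals(N_, 0),
      edge_count(tgt.size(), 0) {}

  void log(double t, int type, int node, long unit) {
    if (!record) return;
    log_t.push_back(t); log_type.push_back(type);
    log_node.push_back(node); log_unit.push_back(unit);
  }

  void log_traj(double t, int node) {
    if (!record) return;
    traj_t.push_back(t); traj_node.push_back(node); traj_n.push_back(nq[node]);
  }

  // clamped accumulation over the window (trans, T]
  void acc(int i, double t) {
    double hi = std::min(t, T);
    double lo = std::max(last_t[i], trans);
    if (hi > lo) {
      cont_int[i] += (hi - lo) * nq[i];
      if (serving[i] >= 0) busy_int[i] += (hi - lo);
    }
    last_t[i] = t;
  }

  void schedule(double t, int type, int node, long unit) {
    Event e; e.t = t; e.seq = seq++; e.type = type; e.node = node; e.unit = unit;
    pq.push(e);
  }

  void start_service(int i, double t, long u) {
    serving[i] = (int)u;
    schedule(t + rexp_inv(mu), 1, i, u);
    log(t, START_SERVICE, i, u);
  }

  void handle_arrival(long u, int i, double t) {
    if (t >= trans && t <= T) {
      if (count_deliveries || dest[u] != i) arrivals[i]++;
    }
    log(t, ARRIVE, i, u);
    if (dest[u] == i) {           // absorbed at destination, never queued
      delivered++;
      log(t, DELIVER, i, u);
      return;
    }
    if (serving[i] < 0) {
      acc(i, t);
      nq[i]++;
      start_service(i, t, u);
      log_traj(t, i);
    } else if ((int)buf[i].size() < K) {
      acc(i, t);
      nq[i]++;
      buf[i].push_back(u);        // front of buffer = most recent
      if ((int)buf[i].size() > maxq[i]) maxq[i] = (int)buf[i].size();
      log_traj(t, i);
    } else {
      // full buffer: oldest queued unit is displaced, newcomer takes front
      long old = buf[i].front();
      buf[i].erase(buf[i].begin());
      buf[i].push_back(u);
      ejected++;
      log(t, EJECT, i, old);
      // contents unchanged: one in, one out
    }
  }

  void handle_completion(int i, double t, long u) {
    int k_out = offsets[i + 1] - offsets[i];
    int pick = (int)std::floor(unif_rand() * k_out);
    if (pick >= k_out) pick = k_out - 1;
    int eid = offsets[i] + pick;
    int j = targets[eid];
    if (t >= trans && t <= T) edge_count[eid]++;
    acc(i, t);
    nq[i]--;
    serving[i] = -1;
    log(t, COMPLETE, i, u);
    log_traj(t, i);
    handle_arrival(u, j, t);
    if (!buf[i].empty() && serving[i] < 0) {
      long u2 = buf[i].back();    // LIFO: most recent queued unit first
      buf[i].pop_back();
      start_service(i, t, u2);
    }
  }

  void run() {
    schedule(rexp_inv(lambda), 0, -1, -1);
    while (!pq.empty()) {
      Event e = pq.top();
      if (e.t > T) break;
      pq.pop();
      if (e.type == 0) {
        int src = (int)std::floor(unif_rand() * N);
        if (src >= N) src = N - 1;
        int d = (int)std::floor(unif_rand() * (N - 1));
        if (d >= N - 1) d = N - 2;
        if (d >= src) d++;
        long u = generated++;
        dest.push_back(d);
        log(e.t, GENERATE, src, u);
        handle_arrival(u, src, e.t);
        schedule(e.t + rexp_inv(lambda), 0, -1, -1);
      } else {
        handle_completion(e.node, e.t, e.unit);
      }
    }
    for (int i = 0; i < N; i++) acc(i, T);
  }

  long residual() const {
    long r = 0;
    for (int i = 0; i < N; i++) {
      if (serving[i] >= 0) r++;
      r += (long)buf[i].size();
    }
    return r;
  }
};

} // namespace

// [[Rcpp::export(name = ".des_run")]]
List des_run(IntegerVector offsets, IntegerVector targets,
             double lambda, double mu, int K, double T, double t_transient,
             bool count_deliveries, bool record_events) {
  int N = offsets.size() - 1;
  std::vector<int> off(offsets.begin(), offsets.end());
  std::vector<int> tgt(targets.begin(), targets.end());
  Engine eng(N, off, tgt, lambda, mu, K, T, t_transient,
             count_deliveries, record_events);
  eng.run();

  List ledger = List::create(
    _["generated"] = (double)eng.generated,
    _["delivered"] = (double)eng.delivered,
    _["ejected"]   = (double)eng.ejected,
    _["residual"]  = (double)eng.residual());

  List out = List::create(
    _["arrivals"]          = NumericVector(eng.arrivals.begin(), eng.arrivals.end()),
    _["busy_time"]         = NumericVector(eng.busy_int.begin(), eng.busy_int.end()),
    _["contents_integral"] = NumericVector(eng.cont_int.begin(), eng.cont_int.end()),
    _["max_queue"]         = IntegerVector(eng.maxq.begin(), eng.maxq.end()),
    _["edge_count"]        = NumericVector(eng.edge_count.begin(), eng.edge_count.end()),
    _["ledger"]            = ledger);

  if (record_events) {
    out["events"] = List::create(
      _["time"] = NumericVector(eng.log_t.begin(), eng.log_t.end()),
      _["type"] = IntegerVector(eng.log_type.begin(), eng.log_type.end()),
      _["node"] = IntegerVector(eng.log_node.begin(), eng.log_node.end()),
      _["unit"] = NumericVector(eng.log_unit.begin(), eng.log_unit.end()));
    out["trajectory"] = List::create(
      _["time"] = NumericVector(eng.traj_t.begin(), eng.traj_t.end()),
      _["node"] = IntegerVector(eng.traj_node.begin(), eng.traj_node.end()),
      _["n"]    = IntegerVector(eng.traj_n.begin(), eng.traj_n.end()));
  }
  return out;
}
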
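>synthetic_alpha_gliadin
MKTFLILALLAIVATTATTAPQGQEPGKQPPPQQQPPQKGQRQGNSQPQQPEPAQGRFQQ
NSQSGQVQSSPPPQPPPGQGQPASAGNGPSGPNQPGPPNPPSPGQSPKQPNSGQQQQPPQ
QSFFILMCVILAAPGSQQQNPPQQPGGQGQQQIFVMLCCIVAIVQVVMVFCFALLVNQPQ
GQQGPQQQQSQQPPPQQGEPNQPQGQPPIPPQQNDPQQQGSQNPQQKGGGGQKLDQGSPD
QQQMMMVLCAIALIVMCIFFLAQQPPPQ
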
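date,max_count
2012-05-01,42600000
2012-10-01,55800000
2013-01-01,61900000
2013-07-01,68400000
2014-02-01,85600000
2014-06-20,389000000
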
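{"schema":"morphospace-v1","base":["f1","f2","f3"],"fibers":{"f1":["0","1"],"f2":["0","1"],"f3":["0","1"]},"admissible":[{"f1":"1","f2":"0","f3":"0"},{"f1":"1","f2":"0","f3":"1"},{"f1":"1","f2":"1","f3":"0"},{"f1":"0","f2":"0","f3":"0"}],"sections":[{"label":"three_extensions","assignment":{"f1":"1"}},{"label":"unextendable","assignment":{"f1":"0","f2":"1"}}]}
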
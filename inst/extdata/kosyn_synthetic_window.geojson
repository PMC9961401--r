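{"type":"Polygon","coordinates":[[[0,0],[30.91,-6.18],[56.67,2.06],[74.18,25.76],[68,53.58],[43.27,65.94],[15.45,59.76],[-4.12,30.91],[0,0]]]}
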
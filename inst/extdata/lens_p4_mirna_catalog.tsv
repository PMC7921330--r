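feature	mean_control
mir-184	15592.3
mir-709	8631.6
mir-31	5871.0
let-7e	3255.7
mir-26a	3129.2
mir-17	2697.1
mir-181a	2298.5
mir-181b	2227.2
mir-125a	2226.9
mir-99b	2181.6
mir-20a	1956.3
let-7c-1	1708.8
mir-24	1397.8
mir-125b	1339.0
mir-103	1280.4
mir-23b	1133.3
mir-23a	1088.0
mir-191	947.9
mir-93	939.8
mir-107	910.4
let-7a	889.8
mir-5105	752.1
mir-16	727.8
mir-5109	684.1
mir-92a	634.0
let-7b	627.0
mir-106a	601.0
mir-130a	594.7
mir-5126	590.7
let-7d	590.4
mir-204	515.4
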
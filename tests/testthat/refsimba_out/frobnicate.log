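subcommand: frobnicate
seed: 1
refsimba version: 0.1.0
config hash: none
started: 2026-09-27T22:34:32
finished: 2026-09-27T22:34:32
subcommand: frobnicate
seed: 1
refsimba version: 0.1.0
config hash: none
started: 2026-09-27T23:19:19
finished: 2026-09-27T23:19:19
subcommand: frobnicate
seed: 1
refsimba version: 0.1.0
config hash: none
started: 2026-09-27T23:49:26
finished: 2026-09-27T23:49:26
subcommand: frobnicate
seed: 1
refsimba version: 0.1.0
config hash: none
started: 2026-09-28T00:12:20
finished: 2026-09-28T00:12:20
subcommand: frobnicate
seed: 1
refsimba version: 0.1.0
config hash: none
started: 2026-09-28T00:51:54
finished: 2026-09-28T00:51:54
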
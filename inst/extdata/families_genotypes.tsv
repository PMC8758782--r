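iid	S192Y	M252R	R402Q
VIII:1	0	1	1
VIII:2	1	0	1
VIII:3	0	1	1
VIII:4	0	0	1
VIII:5	0	1	1
VIII:6	1	0	2
VIII:7	0	1	1
VIII:8	2	0	1
VIII:9	0	1	2
IX:9	1	1	2
IX:10	1	1	2
IX:12	1	1	2
IX:2	0	1	2
IX:14	1	1	2
IX:15	1	1	2
IX:16	1	1	2
IX:21	0	1	2
IX:20	1	1	2
IX:22	1	1	2
IX:1	1	1	1
IX:4	1	1	1
IX:23	1	0	1
IX:24	0	0	1
X:15	1	1	2
X:6	0	1	2
X:8	0	1	2
IX:25	0	1	1
IX:26	0	1	1
X:1	0	2	2
IX:27	0	1	1
IX:28	1	0	1
X:2	1	1	2
IX:29	0	1	1
IX:30	1	0	1
X:3	1	1	2
X:4	1	1	2
X:5	1	1	2
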
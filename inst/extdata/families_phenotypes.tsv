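iid	phenotype
VIII:1	UNAFFECTED
VIII:2	UNAFFECTED
VIII:3	UNAFFECTED
VIII:4	UNAFFECTED
VIII:5	UNAFFECTED
VIII:6	UNAFFECTED
VIII:7	UNAFFECTED
VIII:8	UNAFFECTED
VIII:9	UNAFFECTED
IX:9	AFFECTED_PARTIAL
IX:10	AFFECTED_PARTIAL
IX:12	AFFECTED_PARTIAL
IX:2	UNAFFECTED
IX:14	AFFECTED_PARTIAL
IX:15	AFFECTED_PARTIAL
IX:16	AFFECTED_PARTIAL
IX:21	UNAFFECTED
IX:20	AFFECTED_PARTIAL
IX:22	AFFECTED_PARTIAL
IX:1	UNAFFECTED
IX:4	UNAFFECTED
IX:23	UNAFFECTED
IX:24	UNAFFECTED
X:15	AFFECTED_PARTIAL
X:6	UNAFFECTED
X:8	UNAFFECTED
IX:25	UNAFFECTED
IX:26	UNAFFECTED
X:1	AFFECTED_COMPLETE
IX:27	UNAFFECTED
IX:28	UNAFFECTED
X:2	AFFECTED_PARTIAL
IX:29	UNAFFECTED
IX:30	UNAFFECTED
X:3	AFFECTED_PARTIAL
X:4	AFFECTED_PARTIAL
X:5	AFFECTED_PARTIAL
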
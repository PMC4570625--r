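format-version: 1.2

[Term]
id: GO:0000001
name: root process
namespace: biological_process

[Term]
id: GO:0000002
name: mid branch one
namespace: biological_process
is_a: GO:0000001 ! root process

[Term]
id: GO:0000003
name: mid branch two
namespace: biological_process
is_a: GO:0000001 ! root process

[Term]
id: GO:0000004
name: diamond leaf
namespace: biological_process
is_a: GO:0000002 ! mid branch one
is_a: GO:0000003 ! mid branch two

[Term]
id: GO:0000005
name: deep leaf
namespace: biological_process
is_a: GO:0000004 ! diamond leaf

[Term]
id: GO:0000006
name: branch one child
namespace: biological_process
is_a: GO:0000002 ! mid branch one

[Term]
id: GO:0000007
name: branch two child
namespace: biological_process
is_a: GO:0000003 ! mid branch two

[Term]
id: GO:0000008
name: second diamond
namespace: biological_process
is_a: GO:0000006 ! branch one child
is_a: GO:0000007 ! branch two child

[Term]
id: GO:0000009
name: second diamond child
namespace: biological_process
is_a: GO:0000008 ! second diamond

[Term]
id: GO:0000010
name: obsolete leaf
namespace: biological_process
is_obsolete: true
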